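#' PCA sample scores on gene-centred expression
#'
#' Rows (genes) are centred, components come from the singular value
#' decomposition, and each component's sign is fixed by making its
#' largest-magnitude gene loading positive, so scores are deterministic.
#'
#' @param expression Genes x samples numeric matrix.
#' @param n_components Number of components to return (default 2).
#' @return An object of class `hb_pca`: list with `sample_ids`, `scores`
#'   (samples x components), `explained_variance_ratio` (per retained
#'   component, non-increasing).
#' @export
pca_scores <- function(expression, n_components = 2L) {
  expression <- validate_expression(expression)
  n <- ncol(expression)
  if (n < 2L) stop("need at least 2 samples for PCA")
  k_max <- min(nrow(expression), n)
  if (n_components > k_max) {
    stop("n_components must be <= min(genes, samples) = ", k_max)
  }
  Xc <- t(expression - rowMeans(expression))   # samples x genes, gene-centred
  sv <- svd(Xc, nu = n_components, nv = n_components)
  evr <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  for (k in seq_len(n_components)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) scores[, k] <- -scores[, k]
  }
  dimnames(scores) <- list(colnames(expression),
                           paste0("PC", seq_len(n_components)))
  structure(list(sample_ids = colnames(expression), scores = scores,
                 explained_variance_ratio = evr[seq_len(n_components)]),
            class = "hb_pca")
}

#' Label-grouping score in PCA space
#'
#' Mean silhouette width of the samples in the retained score space
#' (Euclidean distance) under the given labels. Near 1 means samples group
#' tightly by label; near 0, no grouping; negative, anti-grouping. Labels
#' with a single sample are excluded with a warning.
#'
#' @param scores An `hb_pca` from [pca_scores()].
#' @param labels Per-sample categorical labels (in `sample_ids` order).
#' @return Mean silhouette width, a real in \[-1, 1\].
#' @export
grouping_score <- function(scores, labels) {
  labels <- as.factor(labels)
  if (length(labels) != nrow(scores$scores)) stop("one label per sample required")
  counts <- table(labels)
  singles <- names(counts)[counts < 2L]
  keep <- !(labels %in% singles)
  if (length(singles)) {
    warning("excluding label(s) with a single sample: ",
            paste(singles, collapse = ", "))
  }
  lab <- droplevels(labels[keep])
  if (nlevels(lab) < 2L) stop("need >= 2 labels with >= 2 samples each")
  sil <- cluster::silhouette(as.integer(lab),
                             stats::dist(scores$scores[keep, , drop = FALSE]))
  mean(sil[, "sil_width"])
}
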