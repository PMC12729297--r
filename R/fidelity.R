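#' Two-sided Mann-Whitney-Wilcoxon test
#'
#' The U statistic is computed from rank sums with midranks for ties. The
#' p-value uses the exact null distribution of U when both groups have at
#' most 25 observations and there are no ties, and otherwise a normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param method `"auto"` (branch rule above), `"exact"`, or `"approx"`.
#' @return A list with `U` (statistic for `x`), `p` (two-sided p-value), and
#'   `method` (the branch actually used).
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("empty group")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(method,
                  auto = n1 <= 25L && n2 <= 25L && !ties,
                  exact = TRUE,
                  approx = FALSE)
  if (exact && ties) stop("exact branch is undefined in the presence of ties")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(U = U, p = unname(ht$p.value),
       method = if (exact) "exact" else "approx")
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorted ascending, the k-th smallest p becomes
#' `max_{j<=k} min(1, (m-j+1) p_(j))`; values are returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Significance stars for an adjusted p-value
#'
#' `""` above 0.05, then `*` (<= 0.05), `**` (<= 0.01), `***` (<= 0.001),
#' `****` (<= 0.0001); boundaries inclusive.
#'
#' @param p_adj Numeric vector of adjusted p-values in \[0, 1\].
#' @return Character vector of star labels.
#' @export
stars <- function(p_adj) {
  if (any(!is.finite(p_adj) | p_adj < 0 | p_adj > 1)) stop("p-values must lie in [0, 1]")
  out <- character(length(p_adj))
  out[p_adj <= 0.05] <- "*"
  out[p_adj <= 0.01] <- "**"
  out[p_adj <= 0.001] <- "***"
  out[p_adj <= 0.0001] <- "****"
  out
}

#' Biomarker-fidelity evaluation across correction methods
#'
#' For every (biomarker gene, subtype, unordered batch pair, method) cell,
#' compares the gene's expression between the two batches within the subtype
#' by a two-sided Mann-Whitney test, Holm-adjusts p-values within the chosen
#' family, assigns stars, and classifies each non-baseline cell against the
#' uncorrected baseline: `persisting` (significant before and after
#' correction), `removed` (before only), `introduced` (after only), `absent`
#' (neither). Cells with an undersized group are recorded as skipped, never
#' tested.
#'
#' @param matrices Named list of genes x samples matrices and/or
#'   `hb_correction` objects. Must contain an `"uncorrected"` entry (the
#'   baseline).
#' @param annotation Annotation data.frame with `sample`, `batch`, `subtype`.
#' @param biomarkers Character vector of gene ids to evaluate.
#' @param min_group_size Minimum per-group sample count (default 3).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param family Holm family: `"per_gene_method"` (all subtype x batch-pair
#'   cells sharing gene and method; default), `"per_method"`, or `"global"`.
#' @param pool_subtypes If TRUE, additionally test each (gene, batch pair,
#'   method) across all subtypes pooled. Refused for stratified results,
#'   whose scaling is only comparable within subtype.
#' @return An object of class `hb_fidelity`: list with `cells` (data.frame:
#'   gene, subtype, batch1, batch2, method, n1, n2, U, p_raw, p_adj, stars,
#'   median_diff, rank_biserial, skipped, skip_reason, transition),
#'   `family`, `alpha`, and `summary` (per-method transition counts).
#' @export
evaluate_fidelity <- function(matrices, annotation, biomarkers,
                              min_group_size = 3L, alpha = 0.05,
                              family = c("per_gene_method", "per_method", "global"),
                              pool_subtypes = FALSE) {
  family <- match.arg(family)
  if (!"uncorrected" %in% names(matrices)) stop("baseline 'uncorrected' matrix missing")
  intra_only <- vapply(matrices, function(m)
    inherits(m, "hb_correction") && isTRUE(m$intra_subtype_only), logical(1L))
  if (pool_subtypes && any(intra_only)) {
    stop("cross-subtype pooling refused: method(s) ",
         paste(names(matrices)[intra_only], collapse = ", "),
         " are comparable within subtype only")
  }
  mats <- lapply(matrices, function(m) if (inherits(m, "hb_correction")) m$corrected else m)
  ref <- mats[["uncorrected"]]
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!identical(dim(m), dim(ref)) || !identical(dimnames(m), dimnames(ref))) {
      stop("matrix '", nm, "' does not share genes/samples with the baseline")
    }
  }
  missing_bm <- setdiff(biomarkers, rownames(ref))
  if (length(missing_bm)) stop("biomarker not found: ", paste(missing_bm, collapse = ", "))
  annotation <- validate_annotation(annotation)
  if (is.null(annotation$subtype)) stop("annotation lacks a subtype column")
  ord <- match(colnames(ref), annotation$sample)
  if (anyNA(ord)) stop("annotation does not cover all samples")
  annotation <- annotation[ord, , drop = FALSE]
  batches <- levels(droplevels(annotation$batch))
  pairs <- utils::combn(batches, 2L, simplify = FALSE)
  subtypes <- levels(droplevels(annotation$subtype))
  if (pool_subtypes) subtypes <- c(subtypes, ".pooled")

  rows <- list()
  for (method in names(mats)) {
    m <- mats[[method]]
    for (gene in biomarkers) {
      for (s in subtypes) {
        in_s <- if (s == ".pooled") !is.na(annotation$subtype) else
          !is.na(annotation$subtype) & annotation$subtype == s
        for (pr in pairs) {
          i1 <- in_s & annotation$batch == pr[1L]
          i2 <- in_s & annotation$batch == pr[2L]
          n1 <- sum(i1); n2 <- sum(i2)
          row <- data.frame(gene = gene, subtype = s, batch1 = pr[1L],
                            batch2 = pr[2L], method = method,
                            n1 = n1, n2 = n2, U = NA_real_,
                            p_raw = NA_real_, p_adj = NA_real_, stars = "",
                            median_diff = NA_real_, rank_biserial = NA_real_,
                            skipped = FALSE, skip_reason = "",
                            transition = NA_character_)
          if (n1 < min_group_size || n2 < min_group_size) {
            row$skipped <- TRUE
            row$skip_reason <- paste0("group size ", n1, " vs ", n2,
                                      " below minimum ", min_group_size)
          } else {
            g1 <- m[gene, i1]
            g2 <- m[gene, i2]
            mw <- mann_whitney(g1, g2)
            row$U <- mw$U
            row$p_raw <- mw$p
            row$median_diff <- stats::median(g2) - stats::median(g1)
            row$rank_biserial <- 2 * mw$U / (n1 * n2) - 1
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  cells <- do.call(rbind, rows)

  fam_key <- switch(family,
                    per_gene_method = paste(cells$gene, cells$method),
                    per_method = cells$method,
                    global = rep("all", nrow(cells)))
  tested <- !cells$skipped
  for (k in unique(fam_key[tested])) {
    sel <- tested & fam_key == k
    cells$p_adj[sel] <- holm_adjust(cells$p_raw[sel])
  }
  cells$stars[tested] <- stars(cells$p_adj[tested])

  # transitions vs the uncorrected baseline
  key <- function(d) paste(d$gene, d$subtype, d$batch1, d$batch2)
  base <- cells[cells$method == "uncorrected", , drop = FALSE]
  base_sig <- stats::setNames(!base$skipped & base$p_adj <= alpha, key(base))
  base_tested <- stats::setNames(!base$skipped, key(base))
  nonbase <- cells$method != "uncorrected"
  for (i in which(nonbase)) {
    k <- key(cells[i, ])
    if (cells$skipped[i] || !isTRUE(base_tested[[k]])) next
    sig_now <- cells$p_adj[i] <= alpha
    sig_before <- base_sig[[k]]
    cells$transition[i] <-
      if (sig_before && sig_now) "persisting"
      else if (sig_before) "removed"
      else if (sig_now) "introduced"
      else "absent"
  }

  report <- structure(list(cells = cells, family = family, alpha = alpha),
                      class = "hb_fidelity")
  report$summary <- summarize_transitions(report)
  report
}

#' Per-method transition count table
#'
#' @param report An `hb_fidelity` report.
#' @return A data.frame with one row per non-baseline method and columns
#'   `persisting`, `removed`, `introduced`, `absent`, `skipped`.
#' @export
summarize_transitions <- function(report) {
  cells <- report$cells
  methods <- setdiff(unique(cells$method), "uncorrected")
  labels <- c("persisting", "removed", "introduced", "absent", "skipped")
  out <- as.data.frame(matrix(0L, length(methods), length(labels),
                              dimnames = list(NULL, labels)))
  out <- cbind(data.frame(method = methods), out)
  for (i in seq_along(methods)) {
    sub <- cells[cells$method == methods[i], , drop = FALSE]
    out$skipped[i] <- sum(sub$skipped | (!sub$skipped & is.na(sub$transition)))
    tr <- table(factor(sub$transition, levels = labels[1:4]))
    out[i, labels[1:4]] <- as.integer(tr)
  }
  out
}

#' @export
print.hb_fidelity <- function(x, ...) {
  cat("hb_fidelity:", nrow(x$cells), "cells; Holm family:", x$family,
      "; alpha =", x$alpha, "\n")
  print(x$summary)
  invisible(x)
}

#' Write a fidelity report to TSV (and optionally JSON)
#'
#' @param report An `hb_fidelity` report.
#' @param path Output TSV path (one row per cell).
#' @param json_path Optional JSON mirror including family and alpha.
#' @param header_lines Optional `#`-prefixed comment lines.
#' @return Invisibly, `path`.
#' @export
write_fidelity <- function(report, path, json_path = NULL, header_lines = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  close(con)
  suppressWarnings(utils::write.table(report$cells, path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = length(header_lines) > 0))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(family = report$family, alpha = report$alpha,
                              summary = report$summary, cells = report$cells),
                         json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
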