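#' Read a gene-by-sample expression matrix from tab-separated text
#'
#' The expected dialect is a header row of sample identifiers, a first column
#' of gene (or probe) identifiers, tab separation, UTF-8, and "." as the
#' decimal separator. Values are log-scale expression intensities.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (genes x samples) with gene ids as row names and
#'   sample ids as column names.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 2L) stop("expression table needs a gene id column and at least one sample column")
  gene_ids <- tab[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  sample_ids <- colnames(tab)[-1L]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  vals <- suppressWarnings(vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric or non-finite expression value at gene ",
         gene_ids[bad[1L, 1L]], ", sample ", sample_ids[bad[1L, 2L]])
  }
  validate_expression(vals)
}

#' Write an expression matrix in the package's TSV dialect
#'
#' Values are written with full double precision (17 significant digits) so
#' that a read/write round trip preserves them to well below 1e-12.
#'
#' @param x Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @param header_lines Optional character vector of comment lines (each will
#'   be prefixed with `#`) written before the table.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path, header_lines = NULL) {
  x <- validate_expression(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  body <- apply(format(x, digits = 17, trim = TRUE, scientific = FALSE), 1L,
                paste, collapse = "\t")
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Requires tab-separated text with a header containing at least `sample` and
#' `batch` columns; `subtype` and any further covariate columns are optional.
#' Categorical levels are recorded in order of first appearance.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per sample; `batch` (and `subtype`, if
#'   present) are factors with first-appearance level order.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", comment.char = "#")
  validate_annotation(tab)
}

#' Write a sample annotation table
#' @param ann Annotation data.frame as returned by [read_annotation()].
#' @param path Output path.
#' @param header_lines Optional `#`-prefixed comment lines.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(ann, path, header_lines = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  out <- ann
  for (j in seq_along(out)) out[[j]] <- as.character(out[[j]])
  writeLines(paste(colnames(out), collapse = "\t"), con)
  if (nrow(out)) writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  invisible(path)
}

validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup)) stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  dup <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup)) stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  if (any(!is.finite(x))) stop("expression matrix contains missing or non-finite entries")
  x
}

validate_annotation <- function(ann) {
  if (!is.data.frame(ann)) stop("annotation must be a data.frame")
  for (col in c("sample", "batch")) {
    if (!col %in% colnames(ann)) stop("missing column: ", col)
  }
  ann$sample <- as.character(ann$sample)
  dup <- unique(ann$sample[duplicated(ann$sample)])
  if (length(dup)) stop("duplicate sample ids in annotation: ", paste(dup, collapse = ", "))
  b <- as.character(ann$batch)
  if (any(is.na(b) | !nzchar(b))) {
    stop("empty batch label for sample(s): ",
         paste(ann$sample[is.na(b) | !nzchar(b)], collapse = ", "))
  }
  # first-appearance level order for fresh character input; an existing
  # factor keeps its level order so that align() is idempotent
  if (!is.factor(ann$batch)) ann$batch <- factor(b, levels = unique(b))
  if ("subtype" %in% colnames(ann) && !is.factor(ann$subtype)) {
    s <- as.character(ann$subtype)
    s[!is.na(s) & !nzchar(s)] <- NA
    ann$subtype <- factor(s, levels = unique(s[!is.na(s)]))
  }
  rownames(ann) <- NULL
  ann
}

#' Align an expression matrix with its sample annotation
#'
#' Reorders annotation rows to the expression column order and bundles the two
#' into a dataset object. Genes with zero variance across all samples are
#' dropped with a warning: downstream correction divides by the pooled
#' standard deviation, which would be zero for them.
#'
#' @param expression Numeric genes x samples matrix.
#' @param annotation Annotation data.frame (`sample`, `batch`, optional
#'   `subtype` and covariates).
#' @return An object of class `hb_dataset`: a list with elements `expression`
#'   and `annotation`, column/row order aligned.
#' @export
align <- function(expression, annotation) {
  expression <- validate_expression(expression)
  annotation <- validate_annotation(annotation)
  es <- colnames(expression)
  as_ <- annotation$sample
  if (!setequal(es, as_)) {
    only_e <- setdiff(es, as_)
    only_a <- setdiff(as_, es)
    stop("sample sets differ between expression and annotation; ",
         "only in expression: {", paste(only_e, collapse = ", "), "}; ",
         "only in annotation: {", paste(only_a, collapse = ", "), "}")
  }
  annotation <- annotation[match(es, as_), , drop = FALSE]
  rownames(annotation) <- NULL
  v <- apply(expression, 1L, stats::var)
  zero <- v <= 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance gene(s): ",
            paste(rownames(expression)[zero], collapse = ", "))
    expression <- expression[!zero, , drop = FALSE]
  }
  structure(list(expression = expression, annotation = annotation),
            class = "hb_dataset")
}

#' @export
print.hb_dataset <- function(x, ...) {
  cat("hb_dataset:", nrow(x$expression), "genes x", ncol(x$expression), "samples;",
      nlevels(x$annotation$batch), "batches")
  if (!is.null(x$annotation$subtype)) {
    cat(";", nlevels(x$annotation$subtype), "subtype levels")
  }
  cat("\n")
  invisible(x)
}
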