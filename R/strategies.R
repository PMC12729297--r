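#' Specify a batch-correction strategy
#'
#' The four evaluated strategies: plain parametric EB, plain non-parametric
#' EB, subtype-as-covariate parametric EB, and subtype-stratified correction
#' (split by subtype, correct each stratum independently).
#'
#' @param name One of `"parametric"`, `"nonparametric"`, `"covariate"`,
#'   `"stratified"`.
#' @param base_mode Internal EB mode used by the stratified strategy
#'   (`"parametric"`, `"nonparametric"`, or `"none"`).
#' @param covariates Covariate columns for the covariate strategy (default
#'   `"subtype"`).
#' @param min_stratum_size Minimum samples per batch within a subtype stratum
#'   for the stratified strategy (default 3).
#' @param small_stratum_policy What to do with an undersized stratum:
#'   `"error"` (default) or `"skip_uncorrected"` (pass the stratum through
#'   uncorrected, recording a warning).
#' @return A `hb_strategy` list.
#' @export
strategy_spec <- function(name = c("parametric", "nonparametric", "covariate", "stratified"),
                          base_mode = "parametric",
                          covariates = "subtype",
                          min_stratum_size = 3L,
                          small_stratum_policy = c("error", "skip_uncorrected")) {
  name <- match.arg(name)
  base_mode <- match.arg(base_mode, c("parametric", "nonparametric", "none"))
  if (min_stratum_size < 2L) stop("min_stratum_size must be >= 2")
  structure(list(name = name, base_mode = base_mode, covariates = covariates,
                 min_stratum_size = as.integer(min_stratum_size),
                 small_stratum_policy = match.arg(small_stratum_policy)),
            class = "hb_strategy")
}

#' Run one correction strategy on a dataset
#'
#' Dispatches to the corresponding correction: plain parametric and
#' non-parametric run EB correction with no covariates; the covariate
#' strategy protects subtype in the linear model (dummy-coded with the most
#' frequent level as reference); the stratified strategy delegates to
#' [stratified_correct()]. Samples lacking a subtype label are excluded, with
#' a warning, from the subtype-aware strategies.
#'
#' @param dataset An `hb_dataset`.
#' @param spec A `hb_strategy` from [strategy_spec()].
#' @param tol,max_iter Convergence control passed to the EB core.
#' @return An object of class `hb_correction`: list with `corrected` matrix,
#'   `strategy`, `models` (named list of `hb_ebmodel`s; one entry per subtype
#'   for the stratified strategy), `warnings` (character), and
#'   `intra_subtype_only` flag (TRUE only for stratified results).
#' @export
run_strategy <- function(dataset, spec, tol = 1e-4, max_iter = 5000L) {
  if (!inherits(spec, "hb_strategy")) stop("spec must come from strategy_spec()")
  warnings_out <- character()
  if (spec$name %in% c("covariate", "stratified")) {
    st <- dataset$annotation$subtype
    if (is.null(st)) stop("strategy '", spec$name, "' requires subtype labels")
    if (anyNA(st)) {
      drop_ids <- dataset$annotation$sample[is.na(st)]
      warnings_out <- c(warnings_out,
                        paste0("excluded ", length(drop_ids),
                               " sample(s) with missing subtype: ",
                               paste(drop_ids, collapse = ", ")))
      warning(warnings_out[length(warnings_out)])
      keep <- !is.na(st)
      dataset <- structure(list(
        expression = dataset$expression[, keep, drop = FALSE],
        annotation = droplevels(dataset$annotation[keep, , drop = FALSE])),
        class = "hb_dataset")
    }
  }
  res <- switch(spec$name,
    parametric = {
      fit <- combat(dataset, covariates = character(), mode = "parametric",
                    tol = tol, max_iter = max_iter)
      list(corrected = fit$corrected, models = list(all = fit$model))
    },
    nonparametric = {
      fit <- combat(dataset, covariates = character(), mode = "nonparametric")
      list(corrected = fit$corrected, models = list(all = fit$model))
    },
    covariate = {
      fit <- combat(dataset, covariates = spec$covariates, mode = "parametric",
                    tol = tol, max_iter = max_iter, ref_level = "most_frequent")
      list(corrected = fit$corrected, models = list(all = fit$model))
    },
    stratified = return(stratified_correct(dataset, spec, tol = tol,
                                           max_iter = max_iter,
                                           extra_warnings = warnings_out))
  )
  structure(list(corrected = res$corrected, strategy = spec,
                 models = res$models, warnings = warnings_out,
                 intra_subtype_only = FALSE),
            class = "hb_correction")
}

#' Subtype-stratified batch correction
#'
#' Splits samples by subtype, batch-corrects each stratum independently with
#' the strategy's base mode and no covariates, then reassembles columns in
#' the original order. Because each subtype acquires its own scaling
#' parameters, the result is flagged `intra_subtype_only`: cross-subtype
#' contrasts on it are unreliable and are refused downstream.
#'
#' A stratum qualifies only if at least two batches are represented in it and
#' every represented batch contributes at least `min_stratum_size` samples;
#' otherwise the `small_stratum_policy` applies (abort, or pass the stratum
#' through uncorrected with a recorded warning). EB correction on very small
#' subtype groups is unstable, so silent correction of such strata is never
#' performed.
#'
#' @inheritParams run_strategy
#' @param extra_warnings Internal: warnings accumulated by the caller.
#' @return An `hb_correction` with one EB model per corrected stratum.
#' @export
stratified_correct <- function(dataset, spec, tol = 1e-4, max_iter = 5000L,
                               extra_warnings = character()) {
  st <- droplevels(dataset$annotation$subtype)
  if (is.null(st)) stop("stratified correction requires subtype labels")
  corrected <- dataset$expression
  models <- list()
  warnings_out <- extra_warnings
  for (s in levels(st)) {
    idx <- which(st == s)
    ann_s <- droplevels(dataset$annotation[idx, , drop = FALSE])
    counts <- table(ann_s$batch)
    undersized <- counts < spec$min_stratum_size
    ok <- length(counts) >= 2L && !any(undersized)
    if (!ok) {
      detail <- paste0("subtype ", s, ": ",
                       if (length(counts) < 2L) "fewer than 2 batches represented"
                       else paste0("batch ", paste(names(counts)[undersized], collapse = ", "),
                                   " has ", paste(counts[undersized], collapse = ", "),
                                   " sample(s) (< ", spec$min_stratum_size, ")"))
      if (spec$small_stratum_policy == "error") {
        stop("undersized stratum: ", detail)
      }
      msg <- paste0("stratum left uncorrected - ", detail)
      warnings_out <- c(warnings_out, msg)
      warning(msg)
      next
    }
    sub <- structure(list(expression = dataset$expression[, idx, drop = FALSE],
                          annotation = ann_s),
                     class = "hb_dataset")
    fit <- combat(sub, covariates = character(), mode = spec$base_mode,
                  tol = tol, max_iter = max_iter)
    corrected[, idx] <- fit$corrected
    models[[s]] <- fit$model
  }
  structure(list(corrected = corrected, strategy = spec, models = models,
                 warnings = warnings_out, intra_subtype_only = TRUE),
            class = "hb_correction")
}

#' @export
print.hb_correction <- function(x, ...) {
  cat("hb_correction:", x$strategy$name, "strategy;",
      nrow(x$corrected), "genes x", ncol(x$corrected), "samples")
  if (isTRUE(x$intra_subtype_only)) cat("; intra-subtype comparisons only")
  cat("\n")
  if (length(x$warnings)) cat("warnings:", length(x$warnings), "\n")
  invisible(x)
}
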