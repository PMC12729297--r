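#' Simulation configuration for heterogeneous multi-batch expression data
#'
#' Describes a gene x sample log-expression study with subtype-specific
#' means, per-batch per-gene location effects (normal with SD
#' `batch_location_sd`) and squared-scale effects (inverse-gamma with shape
#' `batch_scale_shape` and rate `batch_scale_rate`; an infinite shape pins
#' every squared-scale effect at exactly 1), residual noise, and per-batch
#' subtype composition.
#'
#' @param n_genes Number of genes.
#' @param batches Named integer vector: samples per batch.
#' @param subtype_levels Subtype labels (default the five canonical breast
#'   cancer intrinsic subtypes).
#' @param composition Batch x subtype matrix of subtype probabilities; rows
#'   must sum to 1.
#' @param subtype_means Gene x subtype matrix of true log-expression means.
#' @param biomarker_ids Gene ids flagged as biomarkers (must be row names of
#'   `subtype_means`).
#' @param batch_location_sd SD of the per-gene additive batch effect
#'   (log2 units); 0 gives exactly null location effects.
#' @param batch_scale_shape,batch_scale_rate Inverse-gamma parameters for the
#'   squared scale effect; shape must exceed 2 (finite variance) or be `Inf`
#'   (degenerate at 1).
#' @param noise_sd Residual SD (log2 units).
#' @param seed Integer seed; all draws flow from it.
#' @return A `hb_simconfig` list.
#' @export
sim_config <- function(n_genes,
                       batches,
                       subtype_levels = c("Basal", "LumA", "LumB", "Her2", "Normal"),
                       composition,
                       subtype_means,
                       biomarker_ids = character(),
                       batch_location_sd = 0.5,
                       batch_scale_shape = 4,
                       batch_scale_rate = 3,
                       noise_sd = 1,
                       seed = 1L) {
  if (n_genes < 2L) stop("invalid n_genes: need >= 2")
  if (is.null(names(batches)) || any(batches < 2L)) {
    stop("invalid batches: need a named vector with >= 2 samples per batch")
  }
  composition <- as.matrix(composition)
  if (nrow(composition) != length(batches) ||
      ncol(composition) != length(subtype_levels)) {
    stop("invalid composition: need a ", length(batches), " x ",
         length(subtype_levels), " matrix")
  }
  if (any(abs(rowSums(composition) - 1) > 1e-8) || any(composition < 0)) {
    stop("invalid composition: rows must be probability vectors summing to 1")
  }
  subtype_means <- as.matrix(subtype_means)
  if (!identical(dim(subtype_means), c(as.integer(n_genes), length(subtype_levels)))) {
    stop("invalid subtype_means: need a ", n_genes, " x ",
         length(subtype_levels), " matrix")
  }
  if (is.null(rownames(subtype_means))) {
    rownames(subtype_means) <- sprintf("gene_%04d", seq_len(n_genes))
  }
  colnames(subtype_means) <- subtype_levels
  bad <- setdiff(biomarker_ids, rownames(subtype_means))
  if (length(bad)) stop("invalid biomarker_ids: ", paste(bad, collapse = ", "))
  if (!is.infinite(batch_scale_shape) && batch_scale_shape <= 2) {
    stop("invalid batch_scale_shape: must exceed 2 for finite prior variance")
  }
  if (noise_sd <= 0) stop("invalid noise_sd: must be > 0")
  rownames(composition) <- names(batches)
  colnames(composition) <- subtype_levels
  structure(list(n_genes = as.integer(n_genes), batches = batches,
                 subtype_levels = subtype_levels, composition = composition,
                 subtype_means = subtype_means, biomarker_ids = biomarker_ids,
                 batch_location_sd = batch_location_sd,
                 batch_scale_shape = batch_scale_shape,
                 batch_scale_rate = batch_scale_rate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "hb_simconfig")
}

#' Generate a synthetic dataset with retained ground truth
#'
#' Data follow exactly the location-scale model the correction assumes:
#' \deqn{Y_{jg} = \mu_{s(j),g} + \gamma_{b(j),g} + \delta_{b(j),g}
#'   \varepsilon_{jg}, \quad \varepsilon \sim N(0, \mathrm{noise\_sd}^2),}
#' with subtypes assigned per batch by the configured composition. All
#' randomness flows from `config$seed`; repeated calls are bit-identical.
#'
#' @param config A `hb_simconfig`.
#' @return A list with `dataset` (an `hb_dataset`) and `truth` (class
#'   `hb_truth`: `gamma_true`, `delta2_true` (batch x gene),
#'   `subtype_assignments`, `subtype_means`, `noise_sd`, `n_per_batch`).
#' @export
generate <- function(config) {
  if (!inherits(config, "hb_simconfig")) stop("config must come from sim_config()")
  set.seed(config$seed)
  G <- config$n_genes
  genes <- rownames(config$subtype_means)
  batch_names <- names(config$batches)
  nb <- length(batch_names)

  gamma_true <- matrix(
    if (config$batch_location_sd > 0)
      stats::rnorm(nb * G, 0, config$batch_location_sd) else 0,
    nb, G, dimnames = list(batch_names, genes))
  delta2_true <- matrix(
    if (is.infinite(config$batch_scale_shape)) 1 else
      1 / stats::rgamma(nb * G, shape = config$batch_scale_shape,
                        rate = config$batch_scale_rate),
    nb, G, dimnames = list(batch_names, genes))

  sample_ids <- character()
  batch_lab <- character()
  subtype_lab <- character()
  cols <- list()
  for (b in batch_names) {
    n_b <- config$batches[[b]]
    st <- sample(config$subtype_levels, n_b, replace = TRUE,
                 prob = config$composition[b, ])
    mu <- config$subtype_means[, st, drop = FALSE]            # G x n_b
    eps <- matrix(stats::rnorm(G * n_b, 0, config$noise_sd), G, n_b)
    cols[[b]] <- mu + gamma_true[b, ] + sqrt(delta2_true[b, ]) * eps
    sample_ids <- c(sample_ids, sprintf("%s_s%04d", b, seq_len(n_b)))
    batch_lab <- c(batch_lab, rep(b, n_b))
    subtype_lab <- c(subtype_lab, st)
  }
  expr <- do.call(cbind, cols)
  dimnames(expr) <- list(genes, sample_ids)
  ann <- data.frame(sample = sample_ids, batch = batch_lab,
                    subtype = subtype_lab, stringsAsFactors = FALSE)
  dataset <- suppressWarnings(align(expr, ann))
  truth <- structure(list(gamma_true = gamma_true, delta2_true = delta2_true,
                          subtype_assignments = stats::setNames(subtype_lab, sample_ids),
                          subtype_means = config$subtype_means,
                          noise_sd = config$noise_sd,
                          n_per_batch = table(factor(batch_lab, levels = batch_names))),
                     class = "hb_truth")
  list(dataset = dataset, truth = truth)
}

#' Batch-parameter recovery metrics against simulation ground truth
#'
#' Only contrasts of batch location effects are identifiable: the
#' batch-size-weighted mean of gamma per gene is absorbed into the grand
#' mean during standardization, and estimates live on the per-gene
#' sigma-standardized scale. Estimates are therefore rescaled by the pooled
#' sigma back to log2 units and compared with the batch-size-weighted-centred
#' true gamma. Scale effects are compared as raw-scale within-batch variances
#' (delta2 x sigma2 vs delta2_true x noise_sd^2).
#'
#' @param truth A `hb_truth` from [generate()].
#' @param model An `hb_ebmodel` (from [combat()]'s `model` element).
#' @param estimate Which location estimate to score: `"star"` (posterior,
#'   default) or `"hat"` (per-batch method of moments).
#' @return A list with `location_rmse`, `location_r`, `scale_rmse`
#'   (averaged over batches) and per-batch vectors `location_r_by_batch`,
#'   `location_rmse_by_batch`.
#' @export
recovery_metrics <- function(truth, model, estimate = c("star", "hat")) {
  estimate <- match.arg(estimate)
  lev <- model$batch_levels
  if (!all(lev %in% rownames(truth$gamma_true))) {
    stop("batch labels of model and truth do not match")
  }
  genes <- colnames(model$gamma_hat)
  sigma <- sqrt(model$sigma2_pooled[genes])
  w <- as.numeric(model$n_per_batch[lev]) / sum(model$n_per_batch[lev])
  g_true <- truth$gamma_true[lev, genes, drop = FALSE]
  g_true_c <- sweep(g_true, 2L, colSums(g_true * w))   # identifiable contrasts
  g_est <- if (estimate == "star") model$gamma_star else model$gamma_hat
  g_est_raw <- sweep(g_est[lev, genes, drop = FALSE], 2L, sigma, `*`)
  d_est <- if (estimate == "star") model$delta2_star else model$delta2_hat
  d_est_raw <- sweep(d_est[lev, genes, drop = FALSE], 2L, model$sigma2_pooled[genes], `*`)
  d_true_raw <- truth$delta2_true[lev, genes, drop = FALSE] * truth$noise_sd^2

  r_b <- vapply(lev, function(b) stats::cor(g_est_raw[b, ], g_true_c[b, ]), numeric(1L))
  rmse_b <- vapply(lev, function(b) sqrt(mean((g_est_raw[b, ] - g_true_c[b, ])^2)), numeric(1L))
  scale_b <- vapply(lev, function(b) sqrt(mean((d_est_raw[b, ] - d_true_raw[b, ])^2)), numeric(1L))
  list(location_rmse = mean(rmse_b), location_r = mean(r_b),
       scale_rmse = mean(scale_b),
       location_r_by_batch = r_b, location_rmse_by_batch = rmse_b)
}

# Subtype mean matrix used by the presets: biomarker-like genes get strong
# subtype separation (2-4 log2 units); a slice of background genes carries
# moderate subtype structure (as PAM50-adjacent genes do); the rest are flat.
preset_subtype_means <- function(n_genes, subtype_levels, structured_frac = 0.1) {
  G <- n_genes
  genes <- c("ESR1", "ERBB2", "AURKA", sprintf("gene_%04d", seq_len(G - 3L)))
  mu <- matrix(stats::rnorm(G, mean = 8, sd = 1), G, length(subtype_levels),
               dimnames = list(genes, subtype_levels))
  #            Basal LumA LumB Her2 Normal
  mu["ESR1", ] <- c(7.0, 11.0, 10.5, 7.5, 9.0)
  mu["ERBB2", ] <- c(9.0, 9.0, 9.5, 12.0, 9.0)
  mu["AURKA", ] <- c(10.5, 8.0, 10.0, 9.0, 8.0)
  n_struct <- round(structured_frac * (G - 3L))
  if (n_struct > 0) {
    idx <- 3L + seq_len(n_struct)
    mu[idx, ] <- mu[idx, 1L] +
      matrix(stats::rnorm(n_struct * length(subtype_levels), 0, 1),
             n_struct, length(subtype_levels))
  }
  mu
}

luminal_composition <- function(p_luminal) {
  # split the luminal mass 65/35 between LumA and LumB and the remainder
  # 45/30/25 between Basal, Her2 and Normal-like
  c(Basal = 0.45 * (1 - p_luminal), LumA = 0.65 * p_luminal,
    LumB = 0.35 * p_luminal, Her2 = 0.30 * (1 - p_luminal),
    Normal = 0.25 * (1 - p_luminal))
}

#' Preset: two batches with confounded subtype composition
#'
#' Two batches whose subtype compositions differ along the luminal
#' (hormone-receptor-positive) axis - by default 27.6% vs 60.5% luminal,
#' the ER+ imbalance observed between the METABRIC-style discovery and
#' validation cohorts. Biomarker genes (ESR1, ERBB2, AURKA) get strongly
#' subtype-separated means. With `effect_null = TRUE` the true batch effects
#' are exactly zero (location 0, squared scale 1), so any post-correction
#' within-subtype between-batch difference is method-induced distortion.
#'
#' @param imbalance Length-2 vector of per-batch luminal proportions.
#' @param effect_null If TRUE, zero true batch effects; if FALSE, location
#'   SD 0.5 and inverse-gamma(4, 3) squared scales.
#' @param n_genes Number of genes (default 300).
#' @param n_per_batch Length-2 vector of batch sizes (default 120, 120).
#' @param noise_sd Residual SD (default 1).
#' @param seed Seed for both the preset's mean matrix and the generator.
#' @return A `hb_simconfig`.
#' @export
confounded_preset <- function(imbalance = c(0.276, 0.605), effect_null = TRUE,
                              n_genes = 300L, n_per_batch = c(120L, 120L),
                              noise_sd = 1, seed = 1L) {
  if (any(imbalance <= 0 | imbalance >= 1)) stop("imbalance proportions must lie in (0, 1)")
  subtype_levels <- c("Basal", "LumA", "LumB", "Her2", "Normal")
  set.seed(seed)
  mu <- preset_subtype_means(n_genes, subtype_levels)
  composition <- rbind(b1 = luminal_composition(imbalance[1L]),
                       b2 = luminal_composition(imbalance[2L]))
  sim_config(
    n_genes = n_genes,
    batches = c(b1 = n_per_batch[1L], b2 = n_per_batch[2L]),
    subtype_levels = subtype_levels,
    composition = composition,
    subtype_means = mu,
    biomarker_ids = c("ESR1", "ERBB2", "AURKA"),
    batch_location_sd = if (effect_null) 0 else 0.5,
    batch_scale_shape = if (effect_null) Inf else 4,
    batch_scale_rate = if (effect_null) 1 else 3,
    noise_sd = noise_sd, seed = seed)
}

#' Preset: all-null scenario
#'
#' Balanced subtype composition in both batches and zero true batch effects;
#' batches are statistically exchangeable. Used to measure how often a
#' correction + testing pipeline introduces spurious within-subtype
#' differences.
#'
#' @inheritParams confounded_preset
#' @return A `hb_simconfig`.
#' @export
null_preset <- function(n_genes = 300L, n_per_batch = c(120L, 120L),
                        noise_sd = 1, seed = 1L) {
  confounded_preset(imbalance = c(0.45, 0.45), effect_null = TRUE,
                    n_genes = n_genes, n_per_batch = n_per_batch,
                    noise_sd = noise_sd, seed = seed)
}

#' Preset: METABRIC-like two-cohort study
#'
#' Two batches of 997 and 995 samples (the discovery/validation cohort
#' sizes), luminal-axis composition imbalance 27.6% vs 60.5%, genuine batch
#' effects (location SD 0.5, inverse-gamma(4, 3) squared scales).
#'
#' @param n_genes Number of genes (default 1000).
#' @param seed Seed.
#' @return A `hb_simconfig`.
#' @export
metabric_like_preset <- function(n_genes = 1000L, seed = 1L) {
  confounded_preset(imbalance = c(0.276, 0.605), effect_null = FALSE,
                    n_genes = n_genes, n_per_batch = c(997L, 995L), seed = seed)
}

#' Preset: balanced parameter-recovery scenario
#'
#' A homogeneous cohort (single effective subtype: all subtype means equal
#' per gene) split into two equal batches with genuine location and scale
#' batch effects, for scoring estimator recovery against ground truth
#' without composition confounding.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_per_batch Samples per batch (default 100).
#' @param batch_location_sd True location-effect SD (default 1).
#' @param scale_shape,scale_rate Inverse-gamma parameters (default 4, 3).
#' @param noise_sd Residual SD (default 1).
#' @param seed Seed.
#' @return A `hb_simconfig`.
#' @export
recovery_preset <- function(n_genes = 2000L, n_per_batch = 100L,
                            batch_location_sd = 1, scale_shape = 4,
                            scale_rate = 3, noise_sd = 1, seed = 1L) {
  subtype_levels <- c("Basal", "LumA", "LumB", "Her2", "Normal")
  set.seed(seed)
  base <- stats::rnorm(n_genes, 8, 1)
  mu <- matrix(base, n_genes, length(subtype_levels),
               dimnames = list(sprintf("gene_%04d", seq_len(n_genes)), subtype_levels))
  sim_config(
    n_genes = n_genes,
    batches = c(b1 = n_per_batch, b2 = n_per_batch),
    subtype_levels = subtype_levels,
    composition = matrix(0.2, 2L, 5L),
    subtype_means = mu,
    batch_location_sd = batch_location_sd,
    batch_scale_shape = scale_shape,
    batch_scale_rate = scale_rate,
    noise_sd = noise_sd, seed = seed)
}
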