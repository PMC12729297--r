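#' Build the correction design matrix
#'
#' One indicator column per batch (no intercept), followed by dummy-coded
#' biological covariates with the reference level dropped. The design is
#' checked for full column rank; a covariate that is confounded with batch
#' (e.g. a subtype present in exactly the samples of one batch) is rejected
#' with an informative error.
#'
#' @param annotation Annotation data.frame (`sample`, `batch`, covariates).
#' @param covariates Character vector of annotation column names to include as
#'   biological covariates (may be empty).
#' @param ref_level Reference-level rule for dummy coding: `"first"` (first
#'   appearance order) or `"most_frequent"`.
#' @return A numeric samples x columns design matrix with a `batch_cols`
#'   attribute giving the number of leading batch-indicator columns.
#' @export
build_design <- function(annotation, covariates = character(),
                         ref_level = c("first", "most_frequent")) {
  ref_level <- match.arg(ref_level)
  batch <- annotation$batch
  if (anyNA(batch)) stop("missing batch labels")
  B <- stats::model.matrix(~ 0 + batch)
  colnames(B) <- paste0("batch:", levels(batch))
  blocks <- list(B)
  for (cv in covariates) {
    if (!cv %in% colnames(annotation)) stop("covariate column not found: ", cv)
    col <- annotation[[cv]]
    if (is.numeric(col)) {
      if (anyNA(col)) stop("missing values in covariate: ", cv)
      blocks[[length(blocks) + 1L]] <- matrix(col, ncol = 1L,
                                              dimnames = list(NULL, cv))
      next
    }
    f <- if (is.factor(col)) droplevels(col) else factor(as.character(col))
    if (anyNA(f)) stop("missing values in covariate: ", cv)
    if (ref_level == "most_frequent") {
      f <- stats::relevel(f, ref = names(which.max(table(f))))
    }
    if (nlevels(f) > 1L) {
      D <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(D) <- paste0(cv, ":", levels(f)[-1L])
      blocks[[length(blocks) + 1L]] <- D
    }
    # single-level covariate contributes nothing beyond the batch block
  }
  X <- do.call(cbind, blocks)
  if (qr(X)$rank < ncol(X)) {
    # identify which covariate column lies in the span of the batch block
    nb <- ncol(B)
    offending <- character()
    if (ncol(X) > nb) {
      for (k in (nb + 1L):ncol(X)) {
        fit <- stats::lm.fit(B, X[, k])
        if (max(abs(fit$residuals)) < 1e-8) offending <- c(offending, colnames(X)[k])
      }
    }
    stop("batch confounded with covariate: ",
         if (length(offending)) paste(offending, collapse = ", ") else "design rank deficient")
  }
  structure(X, batch_cols = ncol(B))
}

#' Standardize expression for empirical-Bayes batch modelling
#'
#' Fits, per gene, least squares of expression on the design (batch
#' indicators plus covariates), forms the batch-size-weighted grand mean
#' alpha, the pooled residual variance sigma2 (n denominator), and the
#' standardized residual matrix Z = (Y - alpha - X_cov beta) / sigma.
#'
#' @param dataset An `hb_dataset` from [align()].
#' @param design Design matrix from [build_design()].
#' @return A list of class `hb_standardized` with elements `Z`, `alpha_hat`,
#'   `beta_hat`, `sigma2_pooled`, `stand_mean` (genes x samples matrix
#'   alpha + X_cov beta), and bookkeeping (`batch`, `n_per_batch`).
#' @export
standardize <- function(dataset, design) {
  Y <- dataset$expression
  batch <- dataset$annotation$batch
  n <- ncol(Y)
  if (nrow(design) != n) stop("design rows do not align with dataset samples")
  n_i <- table(batch)
  if (any(n_i < 2L)) {
    stop("each batch needs >= 2 samples; undersized: ",
         paste(names(n_i)[n_i < 2L], collapse = ", "))
  }
  nb <- attr(design, "batch_cols")
  XtX <- crossprod(design)
  coef <- tryCatch(solve(XtX, crossprod(design, t(Y))),
                   error = function(e) stop("singular normal equations: ", conditionMessage(e)))
  batch_coef <- coef[seq_len(nb), , drop = FALSE]          # nb x G
  w <- as.numeric(n_i[match(sub("^batch:", "", rownames(batch_coef)),
                            names(n_i))]) / n
  alpha_hat <- as.numeric(crossprod(batch_coef, w))        # G
  fitted_full <- t(design %*% coef)                        # G x n
  sigma2 <- rowMeans((Y - fitted_full)^2)
  if (any(sigma2 <= 0)) {
    stop("zero pooled residual variance for gene(s): ",
         paste(rownames(Y)[sigma2 <= 0], collapse = ", "))
  }
  if (ncol(design) > nb) {
    beta_hat <- coef[(nb + 1L):ncol(design), , drop = FALSE]
    cov_part <- t(design[, (nb + 1L):ncol(design), drop = FALSE] %*% beta_hat)
  } else {
    beta_hat <- matrix(0, 0L, ncol(coef))
    cov_part <- matrix(0, nrow(Y), n)
  }
  stand_mean <- matrix(alpha_hat, nrow(Y), n) + cov_part
  dimnames(stand_mean) <- dimnames(Y)
  Z <- (Y - stand_mean) / sqrt(sigma2)
  structure(list(Z = Z, alpha_hat = alpha_hat, beta_hat = beta_hat,
                 sigma2_pooled = sigma2, stand_mean = stand_mean,
                 batch = batch, n_per_batch = n_i),
            class = "hb_standardized")
}

#' Per-batch location/scale estimates on the standardized scale
#'
#' gamma_hat is the within-batch mean of Z per gene; delta2_hat the
#' within-batch variance with the n_i denominator.
#'
#' @param std An `hb_standardized` object.
#' @param batches Optional per-sample batch factor (defaults to the one
#'   recorded in `std`).
#' @return An object of class `hb_ebmodel` holding `gamma_hat` and
#'   `delta2_hat` (batch x gene matrices), batch sizes and labels, with
#'   `mode = "none"` until a prior fit is applied.
#' @export
estimate_batch_params <- function(std, batches = std$batch) {
  Z <- std$Z
  batches <- droplevels(as.factor(batches))
  if (nlevels(batches) < 2L) stop("need >= 2 batches")
  n_i <- table(batches)
  if (any(n_i < 2L)) {
    stop("each batch needs >= 2 samples; undersized: ",
         paste(names(n_i)[n_i < 2L], collapse = ", "))
  }
  lev <- levels(batches)
  G <- nrow(Z)
  gamma_hat <- matrix(NA_real_, length(lev), G, dimnames = list(lev, rownames(Z)))
  delta2_hat <- gamma_hat
  for (b in lev) {
    Zb <- Z[, batches == b, drop = FALSE]
    m <- rowMeans(Zb)
    gamma_hat[b, ] <- m
    delta2_hat[b, ] <- rowMeans(Zb * Zb) - m * m
  }
  delta2_hat[delta2_hat < 0] <- 0   # guard tiny negative rounding
  structure(list(gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 n_per_batch = n_i, batch_levels = lev,
                 sigma2_pooled = std$sigma2_pooled,
                 mode = "none",
                 gamma_star = gamma_hat, delta2_star = delta2_hat,
                 iterations = stats::setNames(integer(length(lev)), lev)),
            class = "hb_ebmodel")
}

#' Fit normal / inverse-gamma hyperpriors across genes
#'
#' Per batch: the hyper-mean and hyper-variance of gamma_hat over genes
#' (gamma_bar, tau2; n-1 denominator), and inverse-gamma shape/rate
#' (lambda, theta) for delta2_hat by method of moments:
#' lambda = (2 s2 + m^2)/s2, theta = (m s2 + m^3)/s2, where m and s2 are the
#' across-gene mean and variance of delta2_hat.
#'
#' @param model An `hb_ebmodel` with `gamma_hat`/`delta2_hat` populated.
#' @return The model with `gamma_bar`, `tau2`, `lambda_hyper`, `theta_hyper`
#'   added (named per-batch vectors).
#' @export
fit_hyperpriors <- function(model) {
  if (ncol(model$gamma_hat) < 2L) stop("need >= 2 genes to fit hyperpriors")
  gamma_bar <- rowMeans(model$gamma_hat)
  tau2 <- apply(model$gamma_hat, 1L, stats::var)
  m <- rowMeans(model$delta2_hat)
  s2 <- apply(model$delta2_hat, 1L, stats::var)
  if (any(s2 <= 0)) {
    stop("across-gene variance of delta2_hat is zero for batch(es) ",
         paste(model$batch_levels[s2 <= 0], collapse = ", "),
         "; all genes share one scale - use mode 'none'")
  }
  model$gamma_bar <- gamma_bar
  model$tau2 <- tau2
  model$lambda_hyper <- (2 * s2 + m^2) / s2
  model$theta_hyper <- (m * s2 + m^3) / s2
  model
}

#' Parametric empirical-Bayes posterior estimates
#'
#' Iterates the coupled posterior-mean updates for the location (normal
#' prior) and squared-scale (inverse-gamma prior) batch effects jointly over
#' genes within each batch until the maximum absolute relative change of both
#' falls at or below `tol`:
#' \deqn{\gamma^* = (n_i \tau^2 \hat\gamma + \delta^{2*} \bar\gamma) /
#'       (n_i \tau^2 + \delta^{2*})}
#' \deqn{\delta^{2*} = (\theta + \tfrac12 \sum_j (Z_{jg}-\gamma^*)^2) /
#'       (n_i/2 + \lambda - 1)}
#'
#' @param model An `hb_ebmodel` with hyperpriors fitted.
#' @param Z Standardized matrix (genes x samples).
#' @param batches Per-sample batch factor.
#' @param tol Convergence tolerance on the maximum relative change
#'   (default 1e-4).
#' @param max_iter Iteration cap per batch (default 5000).
#' @return The model with `gamma_star`, `delta2_star`, `iterations` set and
#'   `mode = "parametric"`.
#' @export
eb_parametric <- function(model, Z, batches, tol = 1e-4, max_iter = 5000L) {
  if (is.null(model$tau2)) stop("hyperpriors not fitted")
  if (tol <= 0) stop("tol must be > 0")
  batches <- droplevels(as.factor(batches))
  gamma_star <- model$gamma_hat
  delta2_star <- model$delta2_hat
  iterations <- model$iterations
  for (b in model$batch_levels) {
    Zb <- Z[, batches == b, drop = FALSE]
    n_i <- ncol(Zb)
    S <- rowSums(Zb)            # per gene
    SS <- rowSums(Zb * Zb)
    g <- model$gamma_hat[b, ]
    d <- model$delta2_hat[b, ]
    t2 <- model$tau2[[b]]
    gbar <- model$gamma_bar[[b]]
    lam <- model$lambda_hyper[[b]]
    th <- model$theta_hyper[[b]]
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (n_i * t2 * model$gamma_hat[b, ] + d * gbar) / (n_i * t2 + d)
      sse <- SS - 2 * g_new * S + n_i * g_new^2
      d_new <- (th + 0.5 * sse) / (n_i / 2 + lam - 1)
      change <- max(abs(g_new - g) / pmax(abs(g), 1e-12),
                    abs(d_new - d) / pmax(abs(d), 1e-12))
      g <- g_new
      d <- d_new
      if (change <= tol) break
      if (it >= max_iter) {
        stop("parametric EB failed to converge for batch ", b, " after ",
             max_iter, " iterations (last max relative change ",
             format(change), ")")
      }
    }
    gamma_star[b, ] <- g
    delta2_star[b, ] <- d
    iterations[[b]] <- it
  }
  model$gamma_star <- gamma_star
  model$delta2_star <- delta2_star
  model$iterations <- iterations
  model$mode <- "parametric"
  model
}

#' Non-parametric empirical-Bayes posterior estimates
#'
#' Monte-Carlo-style integration over the empirical prior: for each target
#' gene, every other gene acts as a donor of (gamma_hat, delta2_hat), weighted
#' by the likelihood of the target gene's standardized data under the donor's
#' parameters. Weights are computed in log space with per-gene max
#' subtraction; the target gene is excluded from its own donor set.
#'
#' @inheritParams eb_parametric
#' @param block Number of target genes processed per block (bounds the size
#'   of the gene x gene weight matrix held in memory).
#' @return The model with `gamma_star`, `delta2_star` set and
#'   `mode = "nonparametric"`.
#' @export
eb_nonparametric <- function(model, Z, batches, block = 512L) {
  batches <- droplevels(as.factor(batches))
  G <- nrow(Z)
  if (G < 2L) stop("need >= 2 genes for non-parametric estimation")
  if (any(model$delta2_hat <= 0)) {
    bad <- which(model$delta2_hat <= 0, arr.ind = TRUE)
    stop("delta2_hat is zero for gene ", colnames(model$delta2_hat)[bad[1L, 2L]],
         " in batch ", rownames(model$delta2_hat)[bad[1L, 1L]],
         "; non-parametric weights undefined")
  }
  gamma_star <- model$gamma_hat
  delta2_star <- model$delta2_hat
  for (b in model$batch_levels) {
    Zb <- Z[, batches == b, drop = FALSE]
    n_i <- ncol(Zb)
    S <- rowSums(Zb)
    SS <- rowSums(Zb * Zb)
    g <- model$gamma_hat[b, ]
    d <- model$delta2_hat[b, ]
    base <- -(n_i / 2) * log(2 * pi * d)        # per donor
    inv2d <- 1 / (2 * d)
    gd <- g / d
    g2d <- g^2 * inv2d * 2                      # g^2 / d
    for (start in seq(1L, G, by = block)) {
      idx <- start:min(start + block - 1L, G)
      # logL[target, donor] = base[donor] - (SS[t] - 2 g[dnr] S[t] + n_i g[dnr]^2) / (2 d[dnr])
      logL <- matrix(base, length(idx), G, byrow = TRUE) -
        outer(SS[idx], inv2d) + outer(S[idx], gd) -
        matrix(n_i / 2 * g2d, length(idx), G, byrow = TRUE)
      logL[cbind(seq_along(idx), idx)] <- -Inf   # leave-one-out
      mx <- apply(logL, 1L, max)
      if (any(!is.finite(mx))) {
        stop("all non-parametric weights underflow for gene ",
             rownames(Z)[idx[which(!is.finite(mx))[1L]]], " in batch ", b)
      }
      W <- exp(logL - mx)
      W <- W / rowSums(W)
      gamma_star[b, idx] <- as.numeric(W %*% g)
      delta2_star[b, idx] <- as.numeric(W %*% d)
    }
  }
  model$gamma_star <- gamma_star
  model$delta2_star <- delta2_star
  model$mode <- "nonparametric"
  model
}

#' Back-transform standardized data with batch effects removed
#'
#' Corrected values are
#' \deqn{Y^*_{jg} = \sigma_g / \sqrt{\delta^{2*}_{i(j)g}} (Z_{jg} -
#'   \gamma^*_{i(j)g}) + \alpha_g + x_j \beta_g.}
#'
#' @param std An `hb_standardized` object.
#' @param model An `hb_ebmodel` with posterior estimates populated.
#' @param batches Per-sample batch factor (defaults to the one in `std`).
#' @return Corrected genes x samples matrix with the input dimnames.
#' @export
adjust <- function(std, model, batches = std$batch) {
  batches <- droplevels(as.factor(batches))
  if (any(model$delta2_star <= 0)) stop("delta2_star must be > 0 for adjustment")
  Z <- std$Z
  out <- Z
  for (b in model$batch_levels) {
    j <- batches == b
    out[, j] <- (Z[, j, drop = FALSE] - model$gamma_star[b, ]) /
      sqrt(model$delta2_star[b, ])
  }
  out <- out * sqrt(std$sigma2_pooled) + std$stand_mean
  dimnames(out) <- dimnames(Z)
  out
}

#' Location-scale empirical-Bayes batch correction
#'
#' Orchestrates design construction, standardization, per-batch parameter
#' estimation, prior fitting and posterior shrinkage (parametric normal /
#' inverse-gamma priors, or the non-parametric empirical prior, or no
#' shrinkage at all), and back-transformation.
#'
#' @param dataset An `hb_dataset` from [align()].
#' @param covariates Character vector of biological covariate columns to
#'   protect in the linear model (e.g. `"subtype"`).
#' @param mode `"parametric"`, `"nonparametric"`, or `"none"` (method-of-
#'   moments estimates used directly, which exactly equalizes within-batch
#'   means and variances per gene).
#' @param tol,max_iter Convergence control for the parametric iteration.
#' @param ref_level Reference-level rule for covariate dummy coding.
#' @return A list with `corrected` (genes x samples matrix) and `model`
#'   (`hb_ebmodel`, including standardization by-products for audit).
#' @export
combat <- function(dataset, covariates = character(),
                   mode = c("parametric", "nonparametric", "none"),
                   tol = 1e-4, max_iter = 5000L,
                   ref_level = c("first", "most_frequent")) {
  mode <- match.arg(mode)
  if (nlevels(droplevels(dataset$annotation$batch)) < 2L) {
    stop("need >= 2 batches for correction")
  }
  design <- build_design(dataset$annotation, covariates, ref_level = match.arg(ref_level))
  std <- standardize(dataset, design)
  model <- estimate_batch_params(std)
  if (mode == "parametric") {
    model <- fit_hyperpriors(model)
    model <- eb_parametric(model, std$Z, std$batch, tol = tol, max_iter = max_iter)
  } else if (mode == "nonparametric") {
    model <- eb_nonparametric(model, std$Z, std$batch)
  }
  corrected <- adjust(std, model)
  model$alpha_hat <- std$alpha_hat
  model$beta_hat <- std$beta_hat
  list(corrected = corrected, model = model)
}

#' Serialize an EB model to a tabular audit data.frame
#'
#' One row per batch x gene with the raw and posterior location/scale
#' estimates, suitable for writing with [write_annotation()]-style TSV.
#'
#' @param model An `hb_ebmodel`.
#' @return A data.frame with columns batch, gene, gamma_hat, delta2_hat,
#'   gamma_star, delta2_star.
#' @export
ebmodel_table <- function(model) {
  genes <- colnames(model$gamma_hat)
  do.call(rbind, lapply(model$batch_levels, function(b) {
    data.frame(batch = b, gene = genes,
               gamma_hat = model$gamma_hat[b, ],
               delta2_hat = model$delta2_hat[b, ],
               gamma_star = model$gamma_star[b, ],
               delta2_star = model$delta2_star[b, ],
               row.names = NULL)
  }))
}
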