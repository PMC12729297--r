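# Shared fixtures and independent oracles used across test files.

# Tiny dataset: one gene, two batches of two samples, no subtype structure.
toy_dataset <- function() {
  expr <- matrix(c(0, 2, 4, 6), 1, 4,
                 dimnames = list("g1", paste0("s", 1:4)))
  ann <- data.frame(sample = paste0("s", 1:4),
                    batch = c("b1", "b1", "b2", "b2"))
  align(expr, ann)
}

# Random multi-gene dataset with batch and subtype labels.
random_dataset <- function(G = 50, n = 20, n_batches = 2, seed = 1,
                           subtypes = c("LumA", "Basal")) {
  set.seed(seed)
  expr <- matrix(rnorm(G * n * n_batches, 8, 1), G, n * n_batches,
                 dimnames = list(sprintf("g%03d", 1:G),
                                 sprintf("s%03d", 1:(n * n_batches))))
  ann <- data.frame(sample = colnames(expr),
                    batch = rep(paste0("b", 1:n_batches), each = n),
                    subtype = sample(subtypes, n * n_batches, replace = TRUE))
  align(expr, ann)
}

# Independent oracle: exact two-sided Mann-Whitney p by full enumeration of
# all C(n1+n2, n1) group labelings (tie-free data only).
enumerate_mw_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  U_all <- apply(idx, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# Independent oracle: Holm step-down exactly as defined (sort ascending,
# adjusted_(k) = max_{j<=k} min(1, (m-j+1) p_(j)), back to input order).
holm_stepdown <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}
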