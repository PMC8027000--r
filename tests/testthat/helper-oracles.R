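# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops and textbook formulas only.

# Partial correlation by residual regression: correlate the residuals of
# lm(X_i ~ all others except j) and lm(X_j ~ all others except i).
pcor_oracle <- function(X) {
  p <- ncol(X)
  out <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      others <- setdiff(seq_len(p), c(i, j))
      if (length(others)) {
        Z <- X[, others, drop = FALSE]
        ri <- stats::residuals(stats::lm.fit(cbind(1, Z), X[, i]))
        rj <- stats::residuals(stats::lm.fit(cbind(1, Z), X[, j]))
      } else {
        ri <- X[, i] - mean(X[, i])
        rj <- X[, j] - mean(X[, j])
      }
      out[i, j] <- out[j, i] <- stats::cor(ri, rj)
    }
  }
  out
}

# Exhaustive KNN imputation oracle: plain loops, RMS distance over shared
# observed samples, mean of the k nearest molecules' observed values in the
# target sample, molecule mean as fallback.
knn_oracle <- function(x, k) {
  p <- ncol(x)
  filled <- x
  cm <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(p)) {
    rows <- which(is.na(x[, j]))
    if (!length(rows)) next
    d <- rep(Inf, p)
    for (l in seq_len(p)) {
      if (l == j) next
      sh <- which(!is.na(x[, j]) & !is.na(x[, l]))
      if (length(sh)) d[l] <- sqrt(mean((x[sh, j] - x[sh, l])^2))
    }
    nb <- order(d)[seq_len(min(k, p - 1))]
    nb <- nb[is.finite(d[nb])]
    for (i in rows) {
      v <- x[i, nb]
      v <- v[!is.na(v)]
      filled[i, j] <- if (length(v)) mean(v) else cm[j]
    }
  }
  filled
}

# Multivariate normal draw whose *sample* covariance equals sigma exactly
# (whiten the centered draw with its own sample covariance, then colour).
rmvn_exact <- function(n, sigma) {
  p <- ncol(sigma)
  z <- matrix(stats::rnorm(n * p), n, p)
  z <- scale(z, center = TRUE, scale = FALSE)
  z <- z %*% solve(chol(stats::cov(z)))
  z %*% chol(sigma)
}

# Plain correlated-normal draw via the Cholesky factor.
rmvn <- function(n, sigma) {
  matrix(stats::rnorm(n * ncol(sigma)), n) %*% chol(sigma)
}

# Draws from the null partial-correlation density
# f0(r; kappa) = (1 - r^2)^((kappa-3)/2) / B(1/2, (kappa-1)/2)
# via r^2 ~ Beta(1/2, (kappa-1)/2) with a random sign.
rnull_pcor <- function(m, kappa) {
  r <- sqrt(stats::rbeta(m, 0.5, (kappa - 1) / 2))
  r * sample(c(-1, 1), m, replace = TRUE)
}

# Small annotated table with planted missingness for preprocessing tests.
toy_table <- function(n = 12, missing = list()) {
  set.seed(99)
  x <- matrix(stats::rlnorm(n * 5, meanlog = 3), n, 5)
  for (m in missing) x[m[1], m[2]] <- NA
  feature_table(x, data.frame(
    molecule_id = paste0("m", 1:5),
    name = paste0("Molecule ", 1:5),
    class = c("chemical", "chemical", "metabolite", "metabolite",
              "metabolite"),
    msi_level = c(1L, 2L, 3L, 2L, 1L)))
}

recovery_config <- function(seed) {
  sim_config(n_samples = 300, n_chemicals = 10, n_metabolites = 20,
             n_blocks = 4, chemical_edge_count = 10,
             pcor_magnitude_range = c(0.3, 0.3),
             censoring_quantile = 0, dilution_sd = 0, seed = seed)
}
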