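test_that("shrinkage intensity behaves across signal regimes", {
  # p = 1: lambda defined as 0 by convention
  one <- shrinkage_correlation(matrix(stats::rnorm(20), 20, 1))
  expect_equal(one$R, matrix(1, 1, 1), ignore_attr = TRUE)
  expect_identical(one$lambda, 0)

  # i.i.d. noise with n < p: shrinkage dominates
  set.seed(42)
  noise <- matrix(stats::rnorm(200), 10, 20)
  expect_gte(shrinkage_correlation(noise)$lambda, 0.5)

  # strong fixed correlation, n >> p: little shrinkage, entries near truth
  sigma <- matrix(0.9, 5, 5); diag(sigma) <- 1
  set.seed(43)
  x <- rmvn(5000, sigma)
  shr <- shrinkage_correlation(x)
  expect_lte(shr$lambda, 0.05)
  off <- upper.tri(shr$R)
  expect_true(all(abs(shr$R[off] - 0.9) < 0.02))

  # zero-variance column named in the error
  bad <- cbind(stats::rnorm(10), rep(2, 10))
  colnames(bad) <- c("ok", "flat")
  expect_error(shrinkage_correlation(bad), "flat")
  expect_error(shrinkage_correlation(matrix(stats::rnorm(4), 2, 2)),
               "at least 3 samples")
})

test_that("shrunken correlation matrix stays positive definite when p >> n", {
  set.seed(9)
  x <- matrix(stats::rnorm(8 * 40), 8, 40)
  shr <- shrinkage_correlation(x)
  ev <- eigen(shr$R, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  pc <- partial_correlations(shr$R)
  expect_true(isSymmetric(pc))
  expect_true(all(abs(pc[upper.tri(pc)]) < 1))
})

test_that("partial correlations match closed form and the
           residual-regression oracle", {
  expect_equal(partial_correlations(diag(4)), diag(4))

  # 3x3 equicorrelated rho: every off-diagonal pcor = rho / (1 + rho)
  rho <- 0.5
  R <- matrix(rho, 3, 3); diag(R) <- 1
  pc <- partial_correlations(R)
  expect_equal(pc[upper.tri(pc)], rep(rho / (1 + rho), 3), tolerance = 1e-10)

  # shrinkage disabled, n >> p: equals correlating residuals after
  # regressing each pair on all remaining variables
  set.seed(10)
  sigma <- diag(10)
  sigma[1, 2] <- sigma[2, 1] <- 0.6
  sigma[3, 4] <- sigma[4, 3] <- -0.4
  x <- rmvn(200, sigma)
  shr <- shrinkage_correlation(x, lambda = 0)
  pc2 <- partial_correlations(shr$R)
  expect_equal(unname(pc2), pcor_oracle(x), tolerance = 1e-8)

  expect_error(partial_correlations(matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("null kappa is recovered from its own density and is robust to a
           signal fraction", {
  set.seed(20)
  r <- rnull_pcor(5000, kappa = 100)
  k_hat <- estimate_null_kappa(r)
  expect_gte(k_hat, 85)
  expect_lte(k_hat, 115)

  # 95% null at kappa = 50 contaminated by 5% strong edges: the trimmed fit
  # stays within 25% of the null kappa
  set.seed(21)
  mix <- c(rnull_pcor(4750, 50), sample(c(-0.5, 0.5), 250, replace = TRUE))
  k_mix <- estimate_null_kappa(mix)
  expect_gt(k_mix, 50 * 0.75)
  expect_lt(k_mix, 50 * 1.25)

  expect_warning(k0 <- estimate_null_kappa(rep(0, 100)), "degenerate")
  expect_identical(k0, Inf)
  expect_error(estimate_null_kappa(rep(0.1, 5)), "at least 10")
})

test_that("p-values are correct tail areas under the null density", {
  pc <- diag(3)
  pc[1, 2] <- pc[2, 1] <- 0
  pc[1, 3] <- pc[3, 1] <- 0.3
  pc[2, 3] <- pc[3, 2] <- -0.3
  p <- pcor_pvalues(pc, kappa = 100)
  expect_true(isSymmetric(p))
  expect_equal(p[1, 2], 1)           # null centre
  expect_equal(p[1, 3], p[2, 3])     # two-sided in |r|

  # Monte-Carlo oracle for kappa = 100, r = 0.3
  set.seed(30)
  draws <- rnull_pcor(1e6, 100)
  mc <- mean(abs(draws) >= 0.3)
  se <- sqrt(mc * (1 - mc) / 1e6)
  expect_lt(abs(p[1, 3] - mc), 3 * se)

  # monotonicity: larger |r| -> smaller p, checked pairwise through the
  # exported interface
  set.seed(31)
  r1 <- stats::runif(1000, 0, 0.98)
  r2 <- r1 + stats::runif(1000, 0, 0.99 - r1)
  pv_of <- function(r) {
    m <- diag(2); m[1, 2] <- m[2, 1] <- r
    pcor_pvalues(m, 100)[1, 2]
  }
  pv1 <- vapply(r1, pv_of, numeric(1))
  pv2 <- vapply(r2, pv_of, numeric(1))
  expect_true(all(pv2 <= pv1))

  bad <- diag(2); bad[1, 2] <- bad[2, 1] <- 1
  expect_error(pcor_pvalues(bad, 100), "< 1")
})

test_that("BH edge selection matches a hand-run step-up and reports the
           realized cutoff", {
  # hand oracle: p = {0.001, 0.2, 0.9}, m = 3, q = 0.1 ->
  # 0.001 <= 1/3 * 0.1 rejected; 0.2 > 2/3 * 0.1; 0.9 > 0.1
  pv <- diag(3)
  pv[1, 2] <- pv[2, 1] <- 0.001
  pv[1, 3] <- pv[3, 1] <- 0.2
  pv[2, 3] <- pv[3, 2] <- 0.9
  sel <- fdr_select(pv, q = 0.1)
  expect_identical(sel$n_rejected, 1L)
  expect_identical(sel$significant[1, 2], 1L)
  expect_identical(sum(sel$significant), 2L)  # symmetric single edge
  expect_equal(sel$pvalue_cutoff, 0.001)

  ones <- matrix(1, 4, 4)
  sel0 <- fdr_select(ones, 0.1)
  expect_identical(sel0$n_rejected, 0L)
  expect_equal(sel0$pvalue_cutoff, 0)

  # significant pairs always satisfy p <= realized cutoff
  set.seed(40)
  pr <- matrix(stats::runif(100), 10, 10)
  pr[lower.tri(pr)] <- t(pr)[lower.tri(pr)]
  diag(pr) <- 1
  s <- fdr_select(pr, 0.2)
  if (s$n_rejected > 0)
    expect_true(all(pr[s$significant == 1] <= s$pvalue_cutoff))
})

test_that("fit_ggm recovers a planted network and is deterministic", {
  cfg <- recovery_config(1)
  ch <- simulate_cohort(cfg)
  tab <- glog_transform(ch$table, offset = 1)
  fit <- fit_ggm(tab, q = 0.1)
  expect_s3_class(fit, "ggm")
  # every true edge significant, false edges within the BH budget
  truth <- ch$model$adjacency
  sig <- fit$significant
  ut <- upper.tri(truth)
  tp <- sum(sig[ut] == 1 & truth[ut] == 1)
  fp <- sum(sig[ut] == 1 & truth[ut] == 0)
  expect_identical(tp, sum(truth[ut]))
  expect_lte(fp, ceiling(0.1 * fit$n_edges) + 2)
  # determinism: same table twice -> identical result (minus the call)
  f2 <- fit_ggm(tab, q = 0.1)
  expect_equal(fit[setdiff(names(fit), "call")],
               f2[setdiff(names(f2), "call")])
  # significant pairs have p <= cutoff
  expect_true(all(fit$pvalues[fit$significant == 1] <= fit$pvalue_cutoff))

  # near-null: identity-truth table yields few edges
  set.seed(50)
  x0 <- matrix(stats::rnorm(300 * 30), 300, 30)
  f0 <- suppressWarnings(fit_ggm(x0, q = 0.1))
  expect_lte(f0$n_edges, 3)

  expect_error(fit_ggm(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("edge tables are canonical, stable and round-trip", {
  cfg <- recovery_config(2)
  ch <- simulate_cohort(cfg)
  fit <- fit_ggm(glog_transform(ch$table, offset = 1))
  et <- edge_table(fit, significant_only = TRUE)
  expect_identical(nrow(et), fit$n_edges)
  expect_true(all(et$molecule_a < et$molecule_b))
  expect_true(all(et$significant))
  f <- tempfile(fileext = ".tsv")
  write_edge_table(et, f)
  back <- read_edge_table(f)
  expect_identical(back$molecule_a, et$molecule_a)
  expect_equal(back$pcor, et$pcor, tolerance = 1e-12)
  expect_equal(back$pvalue, et$pvalue, tolerance = 1e-12)
})

test_that("summary and simulate methods work on a fitted model", {
  cfg <- recovery_config(3)
  ch <- simulate_cohort(cfg)
  prep <- preprocess(ch$table)
  fit <- fit_ggm(prep$table)
  s <- summary(fit)
  expect_s3_class(s, "summary.ggm")
  expect_output(print(s), "edge categories")
  expect_identical(unname(sum(s$edge_categories)), fit$n_edges)
  expect_equal(coef(fit), fit$pcor)
  sims <- simulate(fit, nsim = 2, seed = 1, n = 50)
  expect_length(sims, 2)
  expect_identical(dim(sims[[1]]), c(50L, fit$n_molecules))
})
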