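#' Shrinkage estimate of the correlation matrix
#'
#' Computes the analytic shrinkage estimator
#' `R* = lambda * I + (1 - lambda) * R` where `R` is the empirical
#' correlation matrix and the shrinkage intensity `lambda` is the
#' variance-ratio optimum: the summed estimated sampling variances of the
#' off-diagonal empirical correlations divided by their summed squares,
#' clamped to `[0, 1]`. With `lambda > 0` the estimate is positive definite
#' for any `n`, `p`, which is what makes partial correlations computable when
#' the number of molecules approaches or exceeds the number of samples.
#'
#' @param X numeric matrix, samples in rows, variables in columns. Columns
#'   are standardized internally.
#' @param lambda optional fixed shrinkage intensity in `[0, 1]`; `NULL`
#'   (default) uses the analytic optimum.
#' @return list with `R` (the shrunken correlation matrix) and `lambda`.
#' @export
shrinkage_correlation <- function(X, lambda = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("need at least 3 samples")
  if (anyNA(X)) stop("X must not contain missing values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(X)[sds == 0]
    if (is.null(nm)) nm <- which(sds == 0)
    stop("zero-variance molecule(s): ", paste(nm, collapse = ", "))
  }
  xs <- scale(X)
  if (p == 1) {
    R <- matrix(1, 1, 1, dimnames = list(colnames(X), colnames(X)))
    return(list(R = R, lambda = if (is.null(lambda)) 0 else lambda))
  }
  R_emp <- crossprod(xs) / (n - 1)
  if (is.null(lambda)) {
    # var-hat(r_ij) = n/(n-1)^3 * sum_k (w_kij - wbar_ij)^2 with
    # w_kij = x_ki * x_kj; computed without forming the n x p^2 array
    wbar <- crossprod(xs) / n
    sw2 <- crossprod(xs^2)           # sum_k w_kij^2
    var_r <- n / (n - 1)^3 * (sw2 - n * wbar^2)
    off <- upper.tri(R_emp)
    denom <- sum(R_emp[off]^2)
    lambda <- if (denom == 0) 1 else sum(var_r[off]) / denom
    lambda <- min(1, max(0, lambda))
  } else {
    if (lambda < 0 || lambda > 1) stop("'lambda' must lie in [0, 1]")
  }
  R <- (1 - lambda) * R_emp
  diag(R) <- 1
  dimnames(R) <- list(colnames(X), colnames(X))
  list(R = R, lambda = lambda)
}

#' Partial correlations from a correlation matrix
#'
#' Inverts a symmetric positive-definite (shrunken) correlation matrix and
#' standardizes the negated inverse:
#' `pcor[i,j] = -Omega[i,j] / sqrt(Omega[i,i] * Omega[j,j])` with
#' `Omega = R^-1`; the diagonal is set to 1 by convention. Each entry is the
#' Pearson correlation of molecules i and j conditioned on all remaining
#' molecules.
#'
#' @param R symmetric positive-definite correlation matrix.
#' @return Symmetric matrix of partial correlations with unit diagonal.
#' @export
partial_correlations <- function(R) {
  R <- as.matrix(R)
  if (!isSymmetric(unname(R), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  ch <- tryCatch(chol(R), error = function(e)
    stop("correlation matrix is not positive definite", call. = FALSE))
  omega <- chol2inv(ch)
  pc <- pcor_from_precision(omega)
  pc <- (pc + t(pc)) / 2
  dimnames(pc) <- dimnames(R)
  pc
}

offdiag_values <- function(m) m[upper.tri(m)]

#' Fit the null distribution of partial correlations
#'
#' Under the null of no conditional dependence, partial correlations follow
#' the density `f0(r; kappa) = (1 - r^2)^((kappa - 3) / 2) / B(1/2,
#' (kappa - 1)/2)` on (-1, 1), where `kappa` plays the role of an effective
#' degrees of freedom. `kappa` is estimated by maximum likelihood on the
#' bulk of the observed |pcor| distribution, treating the extreme upper
#' tail as signal; the truncated-density normalization is used so the
#' trimming does not bias the fit.
#'
#' @param pcor partial correlation matrix (or a numeric vector of
#'   off-diagonal values).
#' @param trim fraction of smallest |pcor| values used for the fit,
#'   default 0.9 (the top 10% of |r| is treated as potential signal).
#' @return Estimated `kappa` (> 3). A degenerate all-zero input returns
#'   `Inf` with a warning.
#' @export
estimate_null_kappa <- function(pcor, trim = 0.9) {
  r <- if (is.matrix(pcor)) offdiag_values(pcor) else as.numeric(pcor)
  if (length(r) < 10) stop("need at least 10 off-diagonal values")
  if (any(abs(r) >= 1)) stop("off-diagonal |pcor| must be < 1")
  if (all(r == 0)) {
    warning("degenerate partial-correlation distribution (all zero); ",
            "kappa reported as Inf")
    return(Inf)
  }
  if (trim <= 0 || trim > 1) stop("'trim' must lie in (0, 1]")
  a <- abs(r)
  # signal lives in the upper |r| tail only, so the bulk is the lower `trim`
  # fraction of |r|; the likelihood is normalized for the truncation
  hi <- stats::quantile(a, trim, names = FALSE)
  keep <- r[a <= hi]
  m <- length(keep)
  sl <- sum(log1p(-keep^2))
  # truncated log-likelihood in t = log(kappa - 3)
  negll <- function(t) {
    kap <- 3 + exp(t)
    pr <- stats::pbeta(hi^2, 0.5, (kap - 1) / 2)
    if (pr <= 0) return(Inf)
    -((kap - 3) / 2 * sl - m * lbeta(0.5, (kap - 1) / 2) - m * log(pr))
  }
  opt <- stats::optimize(negll, interval = c(-5, 20))
  3 + exp(opt$minimum)
}

#' Two-sided p-values for partial correlations
#'
#' Tail areas `P(|R| >= |r|)` under the null density
#' `f0(r; kappa)`, computed through the regularized incomplete beta function
#' using the representation `r^2 ~ Beta(1/2, (kappa - 1)/2)`.
#'
#' @param pcor partial correlation matrix.
#' @param kappa null effective degrees of freedom (> 3), from
#'   [estimate_null_kappa()].
#' @return Symmetric matrix of p-values in `[0, 1]`, diagonal set to 1.
#' @export
pcor_pvalues <- function(pcor, kappa) {
  pcor <- as.matrix(pcor)
  off <- row(pcor) != col(pcor)
  if (any(abs(pcor[off]) >= 1))
    stop("off-diagonal |pcor| must be < 1")
  if (!is.finite(kappa)) {
    # degenerate point-mass null: any nonzero pcor is infinitely surprising
    p <- ifelse(pcor == 0, 1, 0)
  } else {
    if (kappa <= 3) stop("'kappa' must exceed 3")
    p <- stats::pbeta(pcor^2, 0.5, (kappa - 1) / 2, lower.tail = FALSE)
  }
  diag(p) <- 1
  dimnames(p) <- dimnames(pcor)
  p
}

#' Benjamini-Hochberg edge selection
#'
#' Applies the BH step-up procedure at level `q` to the `p(p-1)/2` unique
#' off-diagonal p-values and marks the rejected molecule pairs as significant
#' edges. The realized p-value cutoff (largest rejected p-value; 0 if none)
#' is returned so results can be reported in the "significant if p < cutoff"
#' style.
#'
#' @param pvalues symmetric p-value matrix.
#' @param q target false discovery rate in (0, 1), default 0.1.
#' @return list with `significant` (binary symmetric matrix),
#'   `pvalue_cutoff` and `n_rejected`.
#' @export
fdr_select <- function(pvalues, q = 0.1) {
  if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
  pvalues <- as.matrix(pvalues)
  off <- upper.tri(pvalues)
  p <- pvalues[off]
  adj <- stats::p.adjust(p, method = "BH")
  rej <- adj <= q
  sig <- matrix(0L, nrow(pvalues), ncol(pvalues), dimnames = dimnames(pvalues))
  sig[off] <- as.integer(rej)
  sig <- sig + t(sig)
  list(significant = sig,
       pvalue_cutoff = if (any(rej)) max(p[rej]) else 0,
       n_rejected = sum(rej))
}

#' Fit a Gaussian graphical model to a preprocessed feature table
#'
#' The end-to-end estimator: standardizes columns, computes the shrinkage
#' correlation matrix, inverts it to partial correlations, fits the null
#' distribution to the bulk of the partial correlations, converts them to
#' two-sided p-values and selects significant edges by Benjamini-Hochberg at
#' FDR `q`. The result is deterministic given the table.
#'
#' @param table a preprocessed [feature_table()] with no missing values, or a
#'   plain numeric matrix (samples x variables).
#' @param q target false discovery rate, default 0.1.
#' @param lambda optional fixed shrinkage intensity (e.g. 0 to disable
#'   shrinkage when `n > p`); `NULL` uses the analytic optimum.
#' @param trim bulk |pcor| fraction for the null fit, default 0.9.
#' @return An object of class `ggm`: list with `pcor`, `shrinkage_lambda`,
#'   `null_kappa`, `pvalues`, `fdr_threshold`, `significant`,
#'   `pvalue_cutoff`, `n_edges`, sample/variable counts and, when available,
#'   the molecule annotations.
#' @examples
#' cfg <- sim_config(n_samples = 80, n_chemicals = 5, n_metabolites = 15,
#'                   n_blocks = 3, chemical_edge_count = 5,
#'                   censoring_quantile = 0, dilution_sd = 0, seed = 42)
#' cohort <- simulate_cohort(cfg)
#' prep <- preprocess(cohort$table)
#' fit <- fit_ggm(prep$table, q = 0.1)
#' fit
#' @export
fit_ggm <- function(table, q = 0.1, lambda = NULL, trim = 0.9) {
  cl <- match.call()
  if (inherits(table, "feature_table")) {
    X <- table$intensities
    molecules <- table$molecules
  } else {
    X <- as.matrix(table)
    molecules <- NULL
  }
  if (anyNA(X))
    stop("table contains missing values; run preprocess() first")
  shr <- shrinkage_correlation(X, lambda = lambda)
  pc <- partial_correlations(shr$R)
  kappa <- estimate_null_kappa(pc, trim = trim)
  pv <- pcor_pvalues(pc, kappa)
  sel <- fdr_select(pv, q = q)
  structure(list(pcor = pc,
                 shrinkage_lambda = shr$lambda,
                 null_kappa = kappa,
                 pvalues = pv,
                 fdr_threshold = q,
                 significant = sel$significant,
                 pvalue_cutoff = sel$pvalue_cutoff,
                 n_edges = sel$n_rejected,
                 n_samples = nrow(X),
                 n_molecules = ncol(X),
                 molecules = molecules,
                 call = cl),
            class = "ggm")
}

#' @export
print.ggm <- function(x, ...) {
  cat("Gaussian graphical model (shrinkage partial correlations)\n")
  cat("  data: ", x$n_samples, " samples x ", x$n_molecules,
      " molecules\n", sep = "")
  cat("  shrinkage lambda: ", signif(x$shrinkage_lambda, 4),
      "   null kappa: ", signif(x$null_kappa, 5), "\n", sep = "")
  cat("  significant edges at FDR ", x$fdr_threshold, ": ", x$n_edges,
      " (p < ", format(x$pvalue_cutoff, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.ggm <- function(object, ...) {
  et <- edge_table(object, significant_only = TRUE)
  cats <- if (!is.null(object$molecules)) {
    net <- build_network(object)
    classify_edges(net)
  } else NULL
  sig <- object$significant[upper.tri(object$significant)] == 1
  pc <- object$pcor[upper.tri(object$pcor)]
  structure(list(fit = object, edges = et, edge_categories = cats,
                 pcor_range = if (any(sig)) range(pc[sig]) else c(NA, NA)),
            class = "summary.ggm")
}

#' @export
print.summary.ggm <- function(x, ...) {
  print(x$fit)
  if (x$fit$n_edges > 0)
    cat("  significant PCC range: [", signif(x$pcor_range[1], 3), ", ",
        signif(x$pcor_range[2], 3), "]\n", sep = "")
  if (!is.null(x$edge_categories)) {
    cat("  edge categories:\n")
    for (nm in names(x$edge_categories))
      cat("    ", nm, ": ", x$edge_categories[[nm]], "\n", sep = "")
  }
  if (nrow(x$edges)) {
    cat("  top edges:\n")
    top <- utils::head(x$edges[order(x$edges$pvalue), ], 10)
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.ggm <- function(object, ...) object$pcor

#' Simulate new data from a fitted Gaussian graphical model
#'
#' Draws multivariate normal samples whose population correlation matrix is
#' the fitted shrunken correlation matrix implied by the model's partial
#' correlations (reconstructed from the stored precision structure).
#'
#' @param object a fitted `ggm`.
#' @param nsim number of datasets to draw.
#' @param seed optional integer seed.
#' @param n samples per dataset; defaults to the fitted sample count.
#' @param ... unused.
#' @return A list of `nsim` numeric matrices.
#' @export
simulate.ggm <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- object$n_samples
  # rebuild the correlation matrix from the partial correlations:
  # pcor was derived from R via Omega = R^-1; invert the standardization
  pc <- object$pcor
  omega_shape <- -pc
  diag(omega_shape) <- 1
  # omega_shape = D^-1 Omega D^-1 for diagonal D = sqrt(diag(Omega)); any D
  # reproduces the same correlation structure up to scale, so use D = I
  R <- stats::cov2cor(chol2inv(chol(omega_shape)))
  ch <- chol(R)
  lapply(seq_len(nsim), function(s) {
    z <- matrix(stats::rnorm(n * ncol(R)), n, ncol(R))
    x <- z %*% ch
    colnames(x) <- colnames(R)
    x
  })
}

#' Tidy edge table of a fitted model or network
#'
#' Flattens the unique molecule pairs into a data frame with columns
#' `molecule_a`, `molecule_b`, `pcor`, `pvalue`, `significant` — the shape
#' used for reporting chemical-metabolite association tables. Pairs are in
#' canonical order (`molecule_a` < `molecule_b` lexicographically) and sorted
#' by p-value with ties broken by the pair ids, so the output is stable.
#'
#' @param x a `ggm` fit or an `exposure_network`.
#' @param significant_only keep only significant pairs (default `TRUE`).
#' @param ... unused.
#' @return data frame of edges.
#' @export
edge_table <- function(x, ...) UseMethod("edge_table")

#' @rdname edge_table
#' @export
edge_table.ggm <- function(x, significant_only = TRUE, ...) {
  p <- x$n_molecules
  ids <- colnames(x$pcor)
  if (is.null(ids)) ids <- sprintf("V%d", seq_len(p))
  ut <- which(upper.tri(x$pcor), arr.ind = TRUE)
  a <- ids[ut[, 1]]; b <- ids[ut[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(molecule_a = a, molecule_b = b,
                   pcor = x$pcor[ut], pvalue = x$pvalues[ut],
                   significant = x$significant[ut] == 1,
                   stringsAsFactors = FALSE)
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  df <- df[order(df$pvalue, df$molecule_a, df$molecule_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write / read a tidy edge table
#'
#' @param edges data frame from [edge_table()].
#' @param path file path (tab-separated).
#' @return `path` invisibly; `read_edge_table` returns the data frame.
#' @export
write_edge_table <- function(edges, path) {
  utils::write.table(format_edge_df(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

format_edge_df <- function(edges) {
  num <- vapply(edges, is.numeric, logical(1))
  edges[num] <- lapply(edges[num], function(v) format(v, digits = 15,
                                                      trim = TRUE))
  edges
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize the full matrices of a fitted model
#'
#' Writes the partial-correlation and p-value matrices as tab-separated
#' files.
#'
#' @param fit a `ggm`.
#' @param pcor_path,pvalue_path output paths.
#' @return `pcor_path`, invisibly.
#' @export
write_ggm_matrices <- function(fit, pcor_path, pvalue_path) {
  stopifnot(inherits(fit, "ggm"))
  utils::write.table(fit$pcor, pcor_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(fit$pvalues, pvalue_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(pcor_path)
}
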