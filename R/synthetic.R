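#' Simulation configuration for a synthetic exposome-metabolome cohort
#'
#' Parameterizes the synthetic-cohort generator. The defaults emulate the
#' structure of a serum exposome+metabolome study: roughly 140 annotated
#' molecules (50 environmental chemicals, 90 endogenous metabolites) measured
#' in 70-140 samples, metabolites organized in pathway blocks with chain-like
#' partial-correlation structure, a sparse set of chemical-metabolite edges of
#' magnitude 0.12-0.3, left-censored missingness and per-sample dilution
#' scaling.
#'
#' @param n_samples number of samples.
#' @param n_chemicals number of environmental-chemical columns.
#' @param n_metabolites number of endogenous-metabolite columns.
#' @param n_blocks number of metabolite pathway blocks.
#' @param pcor_magnitude_range length-2 numeric in (0,1): range of absolute
#'   partial correlations assigned to true edges.
#' @param chemical_edge_count number of true chemical-metabolite edges; each
#'   chemical carries at most 3 of them (sparse exposures).
#' @param censoring_quantile per-molecule left-censoring fraction in
#'   `[0, 0.5)`: latent values below this quantile are recorded as missing.
#' @param dilution_sd standard deviation (log scale) of the per-sample
#'   multiplicative dilution factor; 0 disables dilution.
#' @param intensity_location,intensity_scale mean and sd of the per-molecule
#'   log-intensity baseline (intensities are `exp(location + scale * z)`).
#' @param neg_edge_prob probability that a chemical-metabolite edge is
#'   negative (metabolite chain edges are positive, mimicking biosynthesis).
#' @param seed integer seed for the generator's random stream.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [make_ground_truth()], [simulate_feature_table()],
#'   [simulate_cohort()]
#' @export
sim_config <- function(n_samples = 140, n_chemicals = 50, n_metabolites = 90,
                       n_blocks = 15,
                       pcor_magnitude_range = c(0.12, 0.3),
                       chemical_edge_count = 25,
                       censoring_quantile = 0.1,
                       dilution_sd = 0.25,
                       intensity_location = 10, intensity_scale = 1,
                       neg_edge_prob = 0.35,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_chemicals = as.integer(n_chemicals),
              n_metabolites = as.integer(n_metabolites),
              n_blocks = as.integer(n_blocks),
              pcor_magnitude_range = as.numeric(pcor_magnitude_range),
              chemical_edge_count = as.integer(chemical_edge_count),
              censoring_quantile = as.numeric(censoring_quantile),
              dilution_sd = as.numeric(dilution_sd),
              intensity_location = as.numeric(intensity_location),
              intensity_scale = as.numeric(intensity_scale),
              neg_edge_prob = as.numeric(neg_edge_prob),
              seed = as.integer(seed))
  counts <- c("n_samples", "n_chemicals", "n_metabolites", "n_blocks")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("'", nm, "' must be a count >= 1")
  r <- cfg$pcor_magnitude_range
  if (length(r) != 2 || any(r <= 0) || any(r >= 1) || r[1] > r[2])
    stop("'pcor_magnitude_range' must be an ordered interval within (0, 1)")
  if (cfg$chemical_edge_count < 1L)
    stop("'chemical_edge_count' must be a count >= 1")
  if (cfg$chemical_edge_count > 3L * cfg$n_chemicals)
    stop("cannot place ", cfg$chemical_edge_count,
         " chemical-metabolite edges: at most 3 per chemical allows ",
         3L * cfg$n_chemicals)
  if (cfg$censoring_quantile < 0 || cfg$censoring_quantile >= 0.5)
    stop("'censoring_quantile' must lie in [0, 0.5) so the 50% missingness ",
         "filter cannot remove molecules by construction")
  if (cfg$dilution_sd < 0) stop("'dilution_sd' must be nonnegative")
  if (cfg$intensity_scale <= 0) stop("'intensity_scale' must be positive")
  if (cfg$n_metabolites < cfg$n_blocks)
    stop("need at least one metabolite per block (n_metabolites < n_blocks)")
  class(cfg) <- "sim_config"
  cfg
}

# Lay out the true edge set implied by a configuration: chain edges inside
# each metabolite block plus sparse chemical->metabolite edges (1-3 per
# chemical). Returns a two-column index matrix (global column indices,
# chemicals first).
plan_edges <- function(cfg) {
  p_c <- cfg$n_chemicals
  p_m <- cfg$n_metabolites
  blocks <- sort(rep(seq_len(cfg$n_blocks), length.out = p_m))
  met_edges <- NULL
  for (b in seq_len(cfg$n_blocks)) {
    idx <- which(blocks == b) + p_c
    if (length(idx) > 1)
      met_edges <- rbind(met_edges, cbind(idx[-length(idx)], idx[-1]))
  }
  max_chem_edges <- 3L * p_c
  if (cfg$chemical_edge_count > max_chem_edges)
    stop("cannot place ", cfg$chemical_edge_count,
         " chemical-metabolite edges: at most 3 per chemical allows ",
         max_chem_edges)
  if (cfg$chemical_edge_count > p_c * p_m)
    stop("more chemical-metabolite edges requested than chemical x ",
         "metabolite pairs available")
  # round-robin so every chemical gets >= 1 edge before any gets a 2nd/3rd
  chem_of_edge <- rep(seq_len(p_c), times = 3)[seq_len(cfg$chemical_edge_count)]
  met_of_edge <- integer(cfg$chemical_edge_count)
  used <- matrix(FALSE, p_c, p_m)
  for (e in seq_along(chem_of_edge)) {
    free <- which(!used[chem_of_edge[e], ])
    m <- free[sample.int(length(free), 1L)]
    used[chem_of_edge[e], m] <- TRUE
    met_of_edge[e] <- m + p_c
  }
  list(edges = rbind(met_edges, cbind(chem_of_edge, met_of_edge)),
       n_met_edges = if (is.null(met_edges)) 0L else nrow(met_edges),
       blocks = blocks)
}

#' Construct a ground-truth Gaussian graphical model
#'
#' Builds a sparse symmetric positive-definite precision matrix whose implied
#' partial correlations realize the configured edge set: chain-structured
#' metabolite pathway blocks (consecutive within-block edges, mimicking
#' biosynthesis chains) plus `chemical_edge_count` sparse chemical-metabolite
#' edges. Positive definiteness is enforced by diagonal loading followed by
#' off-diagonal rescaling so realized edge magnitudes stay inside
#' `pcor_magnitude_range`.
#'
#' @param config a [sim_config()].
#' @return An object of class `ground_truth`: list with `precision_matrix`,
#'   `adjacency`, `true_pcor` (all p x p), `molecule_classes`,
#'   `block_assignments` and `molecule_ids`.
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .make_ground_truth_unseeded(config)
}

.make_ground_truth_unseeded <- function(config) {
  p_c <- config$n_chemicals
  p_m <- config$n_metabolites
  p <- p_c + p_m
  plan <- plan_edges(config)
  edges <- plan$edges
  n_edges <- nrow(edges)
  mag <- stats::runif(n_edges, config$pcor_magnitude_range[1],
                      config$pcor_magnitude_range[2])
  sgn <- rep(1, n_edges)
  if (n_edges > plan$n_met_edges) {
    chem_rows <- (plan$n_met_edges + 1):n_edges
    sgn[chem_rows] <- ifelse(stats::runif(length(chem_rows)) <
                               config$neg_edge_prob, -1, 1)
  }
  target <- mag * sgn

  omega <- diag(p)
  for (e in seq_len(n_edges)) {
    i <- edges[e, 1]; j <- edges[e, 2]
    omega[i, j] <- omega[j, i] <- -target[e]
  }
  # diagonal loading until min eigenvalue >= 1e-3, then rescale off-diagonals
  # so the implied pcor magnitudes hit their targets again; repeat a bounded
  # number of times
  for (iter in 1:50) {
    ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < 1e-3) {
      omega <- omega + (1e-3 - ev + 1e-6) * diag(p)
      d <- diag(omega)
      for (e in seq_len(n_edges)) {
        i <- edges[e, 1]; j <- edges[e, 2]
        omega[i, j] <- omega[j, i] <- -target[e] * sqrt(d[i] * d[j])
      }
    } else break
  }
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop("could not reach a positive-definite precision matrix for the ",
         "requested edge magnitudes; lower pcor_magnitude_range or ",
         "chemical_edge_count")
  pcor <- pcor_from_precision(omega)
  realized <- abs(pcor[edges])
  lo <- config$pcor_magnitude_range[1] - 1e-8
  hi <- config$pcor_magnitude_range[2] + 1e-8
  if (any(realized < lo | realized > hi))
    stop("realized edge partial correlations left the configured range ",
         "after diagonal loading; configuration infeasible")
  adjacency <- matrix(0L, p, p)
  adjacency[edges] <- 1L
  adjacency <- adjacency + t(adjacency)
  ids <- c(sprintf("chem_%02d", seq_len(p_c)),
           sprintf("met_%02d", seq_len(p_m)))
  dimnames(omega) <- dimnames(pcor) <- dimnames(adjacency) <- list(ids, ids)
  structure(list(precision_matrix = omega,
                 adjacency = adjacency,
                 true_pcor = pcor,
                 molecule_classes = c(rep("chemical", p_c),
                                      rep("metabolite", p_m)),
                 block_assignments = c(rep(NA_integer_, p_c), plan$blocks),
                 molecule_ids = ids),
            class = "ground_truth")
}

# partial correlations implied by a precision matrix:
# pcor[i,j] = -omega[i,j] / sqrt(omega[i,i] * omega[j,j]); unit diagonal
pcor_from_precision <- function(omega) {
  d <- 1 / sqrt(diag(omega))
  pc <- -omega * tcrossprod(d)
  diag(pc) <- 1
  pc
}

#' @export
print.ground_truth <- function(x, ...) {
  p <- length(x$molecule_ids)
  cat("ground_truth GGM: ", p, " molecules (",
      sum(x$molecule_classes == "chemical"), " chemicals, ",
      sum(x$molecule_classes == "metabolite"), " metabolites), ",
      sum(x$adjacency[upper.tri(x$adjacency)]), " true edges\n", sep = "")
  invisible(x)
}

#' Simulate an annotated feature table from a ground-truth model
#'
#' Draws latent multivariate normal concentrations from the inverse of the
#' precision matrix, maps them to positive intensities through a per-molecule
#' log-normal baseline, multiplies each sample by a random dilution factor
#' (undone later by sum normalization), and applies per-molecule
#' left-censoring: latent values below the molecule's `censoring_quantile`
#' empirical quantile are recorded as missing, emulating a detection limit.
#'
#' @param model a `ground_truth` object from [make_ground_truth()].
#' @param config the [sim_config()] used to build `model`.
#' @return A [feature_table()] with molecule annotations (class, block,
#'   msi_level) attached, plus attributes `dilution_factors` and
#'   `censor_thresholds` (latent scale).
#' @export
simulate_feature_table <- function(model, config) {
  stopifnot(inherits(model, "ground_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  .simulate_table_unseeded(model, config)
}

.simulate_table_unseeded <- function(model, config) {
  p <- length(model$molecule_ids)
  n <- config$n_samples
  sigma <- chol2inv(chol(model$precision_matrix))
  # draw via the Cholesky factor for exact RNG-stream control
  z <- matrix(stats::rnorm(n * p), n, p)
  latent <- z %*% chol(sigma)
  loc <- stats::rnorm(p, config$intensity_location, 1)
  intens <- exp(sweep(latent * config$intensity_scale, 2, loc, "+"))
  dil <- exp(stats::rnorm(n, 0, config$dilution_sd))
  measured <- intens * dil
  thresholds <- rep(-Inf, p)
  if (config$censoring_quantile > 0) {
    # LOD acts on the latent concentration, so the missingness pattern does
    # not depend on the dilution draw
    thresholds <- apply(latent, 2, stats::quantile,
                        probs = config$censoring_quantile, names = FALSE)
    for (j in seq_len(p)) measured[latent[, j] < thresholds[j], j] <- NA
  }
  msi <- sample(1:3, p, replace = TRUE, prob = c(0.2, 0.4, 0.4))
  mol <- data.frame(molecule_id = model$molecule_ids,
                    name = model$molecule_ids,
                    class = model$molecule_classes,
                    msi_level = msi,
                    block = model$block_assignments,
                    stringsAsFactors = FALSE)
  ft <- feature_table(measured, mol,
                      sample_ids = sprintf("S%03d", seq_len(n)))
  attr(ft, "dilution_factors") <- dil
  attr(ft, "censor_thresholds") <- thresholds
  attr(ft, "latent") <- latent
  ft
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [make_ground_truth()] and
#' [simulate_feature_table()] off a single random stream seeded at
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements `model` (`ground_truth`) and `table`
#'   (`feature_table`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  model <- .make_ground_truth_unseeded(config)
  table <- .simulate_table_unseeded(model, config)
  list(model = model, table = table)
}

#' Write ground-truth matrices as delimited text
#'
#' Writes the adjacency and true partial-correlation matrices of a
#' `ground_truth` model as tab-separated files, for use as test fixtures.
#'
#' @param model a `ground_truth`.
#' @param adjacency_path,pcor_path output file paths.
#' @return `adjacency_path`, invisibly.
#' @export
write_ground_truth <- function(model, adjacency_path, pcor_path) {
  stopifnot(inherits(model, "ground_truth"))
  utils::write.table(model$adjacency, adjacency_path, sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(model$true_pcor, pcor_path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(adjacency_path)
}
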