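#' Remove molecules with too many missing values
#'
#' Drops every molecule whose missing fraction strictly exceeds
#' `max_missing_fraction` (the conventional "more than 50% missing" rule:
#' exactly 50% missing is retained). Samples are never removed and surviving
#' values are untouched.
#'
#' @param table a [feature_table()].
#' @param max_missing_fraction retention threshold in `[0, 1)`; default 0.5.
#' @return list with elements `table` (filtered `feature_table`) and `report`
#'   (data frame of removed molecules with their missing fractions).
#' @export
filter_missingness <- function(table, max_missing_fraction = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  if (max_missing_fraction < 0 || max_missing_fraction >= 1)
    stop("'max_missing_fraction' must lie in [0, 1)")
  frac <- colMeans(is.na(table$intensities))
  drop <- frac > max_missing_fraction
  if (all(drop))
    stop("all molecules exceed the missingness threshold of ",
         max_missing_fraction, "; nothing left to analyse")
  report <- data.frame(molecule_id = table$molecules$molecule_id[drop],
                       missing_fraction = unname(frac[drop]),
                       stringsAsFactors = FALSE)
  out <- if (any(drop)) subset_table(table, molecules = which(!drop))
         else table
  list(table = out, report = report)
}

# RMS distance between two molecule profiles over mutually observed samples;
# +Inf when they share no observed sample
profile_distance <- function(a, b) {
  shared <- !is.na(a) & !is.na(b)
  if (!any(shared)) return(Inf)
  sqrt(mean((a[shared] - b[shared])^2))
}

#' Impute missing intensities by k-nearest molecules
#'
#' Replaces each missing cell by the mean over the molecule's `k` nearest
#' neighbour molecules of their observed values in that sample. Nearness is
#' Euclidean distance between molecule profiles over mutually observed
#' samples, normalized by the number of shared samples (root mean square) so
#' pairs with different overlap are comparable. When none of the `k`
#' neighbours is observed in that sample the cell falls back to the
#' molecule's own observed mean; such cells are listed in the report.
#' Observed values are never altered.
#'
#' @param table a [feature_table()]; every molecule must have at least one
#'   observed value (run [filter_missingness()] first).
#' @param k number of neighbour molecules, default 10.
#' @return list with `table` (complete `feature_table`) and `report` (list
#'   with `imputed_cell_count` and `fallback_cells` data frame).
#' @export
knn_impute <- function(table, k = 10) {
  stopifnot(inherits(table, "feature_table"))
  if (k < 1) stop("'k' must be >= 1")
  x <- table$intensities
  p <- ncol(x)
  obs_count <- colSums(!is.na(x))
  if (any(obs_count == 0))
    stop("molecule(s) with no observed values: ",
         paste(table$molecules$molecule_id[obs_count == 0], collapse = ", "),
         "; run filter_missingness() first")
  miss <- which(is.na(x), arr.ind = TRUE)
  if (nrow(miss) == 0)
    return(list(table = table,
                report = list(imputed_cell_count = 0L,
                              fallback_cells = data.frame())))
  k <- min(k, p - 1L)
  filled <- x
  fallback <- list()
  col_means <- colMeans(x, na.rm = TRUE)
  need <- sort(unique(miss[, 2]))
  for (j in need) {
    d <- vapply(seq_len(p), function(l)
      if (l == j) Inf else profile_distance(x[, j], x[, l]), numeric(1))
    nb <- order(d)[seq_len(k)]
    nb <- nb[is.finite(d[nb])]
    rows <- miss[miss[, 2] == j, 1]
    for (i in rows) {
      vals <- x[i, nb]
      vals <- vals[!is.na(vals)]
      if (length(vals)) {
        filled[i, j] <- mean(vals)
      } else {
        filled[i, j] <- col_means[j]
        fallback[[length(fallback) + 1L]] <-
          data.frame(sample_id = rownames(x)[i],
                     molecule_id = table$molecules$molecule_id[j],
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- table
  out$intensities <- filled
  list(table = out,
       report = list(imputed_cell_count = nrow(miss),
                     fallback_cells = if (length(fallback))
                       do.call(rbind, fallback) else data.frame()))
}

#' Block-wise sample-sum normalization
#'
#' Divides each sample's intensities by that sample's total, separately
#' within the chemical (exposome) and metabolite (metabolome) column blocks,
#' so each sample's block-wise row sum becomes 1. This cancels per-sample
#' dilution and injection-volume variation.
#'
#' @param table a complete (no missing cells) [feature_table()].
#' @return The normalized `feature_table`.
#' @export
sum_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities
  if (anyNA(x)) stop("sum_normalize requires a complete table; impute first")
  if (any(x < 0)) stop("sum_normalize requires nonnegative intensities")
  for (cl in unique(table$molecules$class)) {
    cols <- table$molecules$class == cl
    tot <- rowSums(x[, cols, drop = FALSE])
    zero <- tot <= 0
    if (any(zero))
      stop("zero ", cl, " block total for sample(s): ",
           paste(rownames(x)[zero], collapse = ", "))
    x[, cols] <- x[, cols, drop = FALSE] / tot
  }
  out <- table
  out$intensities <- x
  out
}

#' Generalized log transform
#'
#' Applies the variance-stabilizing transform
#' `glog(x; a) = log2((x + sqrt(x^2 + a^2)) / 2)`, which is defined at zero
#' and tends to `log2(x)` for `x >> a`. The offset `a` is chosen per class
#' block; by default it is the block's smallest positive value, a
#' data-adaptive choice recorded in the result.
#'
#' @param table a complete [feature_table()].
#' @param offset positive scalar, or named numeric vector with one offset per
#'   class block; `NULL` (default) uses each block's minimum positive value.
#' @return The transformed `feature_table`, with attribute `glog_offset`
#'   (named per-block vector).
#' @export
glog_transform <- function(table, offset = NULL) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities
  if (anyNA(x)) stop("glog_transform requires a complete table")
  classes <- unique(table$molecules$class)
  offsets <- numeric(0)
  for (cl in classes) {
    cols <- table$molecules$class == cl
    block <- x[, cols, drop = FALSE]
    a <- if (is.null(offset)) {
      pos <- block[block > 0]
      if (!length(pos)) stop("block '", cl, "' has no positive value to set ",
                             "a default glog offset; supply one")
      min(pos)
    } else if (length(offset) > 1) {
      if (is.null(names(offset)) || !cl %in% names(offset))
        stop("per-block 'offset' must be named by class")
      offset[[cl]]
    } else offset
    if (!is.finite(a) || a <= 0) stop("glog offset must be positive")
    x[, cols] <- glog(block, a)
    offsets[cl] <- a
  }
  out <- table
  out$intensities <- x
  attr(out, "glog_offset") <- offsets
  out
}

#' @rdname glog_transform
#' @param x numeric vector or matrix.
#' @param a positive offset.
#' @export
glog <- function(x, a) log2((x + sqrt(x^2 + a^2)) / 2)

#' @rdname glog_transform
#' @param y glog-transformed values.
#' @export
glog_inverse <- function(y, a) {
  s <- 2^(y + 1)
  (s^2 - a^2) / (2 * s)
}

#' Split / merge chemical and metabolite blocks
#'
#' `split_blocks` separates a table into its chemical and metabolite column
#' blocks; `merge_blocks` reassembles them (chemical columns first), checking
#' that both blocks carry the same samples in the same order.
#'
#' @param table a [feature_table()].
#' @param chemicals,metabolites the two block `feature_table`s.
#' @return `split_blocks`: list with `chemicals` and `metabolites`;
#'   `merge_blocks`: a single `feature_table`.
#' @export
split_blocks <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  list(chemicals = subset_table(table,
                                molecules = table$molecules$class == "chemical"),
       metabolites = subset_table(table,
                                  molecules = table$molecules$class == "metabolite"))
}

#' @rdname split_blocks
#' @export
merge_blocks <- function(chemicals, metabolites) {
  stopifnot(inherits(chemicals, "feature_table"),
            inherits(metabolites, "feature_table"))
  if (!identical(rownames(chemicals$intensities),
                 rownames(metabolites$intensities)))
    stop("sample ids differ between the chemical and metabolite blocks")
  feature_table(cbind(chemicals$intensities, metabolites$intensities),
                rbind(chemicals$molecules, metabolites$molecules))
}

#' Full preprocessing chain
#'
#' Runs the standard LC-MS preprocessing order: missingness filter (more than
#' `max_missing_fraction` missing removed), k-nearest-molecule imputation on
#' raw intensities, block-wise sample-sum normalization, generalized log
#' transform, and reordering to chemicals-then-metabolites.
#'
#' @param table a [feature_table()].
#' @param max_missing_fraction see [filter_missingness()]; default 0.5.
#' @param k see [knn_impute()]; default 10.
#' @param glog_offset see [glog_transform()]; default data-adaptive.
#' @return list with `table` (preprocessed `feature_table`) and `report`
#'   (class `preprocess_report`: removals, imputed-cell count, normalization
#'   mode and realized glog offsets).
#' @export
preprocess <- function(table, max_missing_fraction = 0.5, k = 10,
                       glog_offset = NULL) {
  filt <- filter_missingness(table, max_missing_fraction)
  imp <- knn_impute(filt$table, k = k)
  norm <- sum_normalize(imp$table)
  gl <- glog_transform(norm, glog_offset)
  blocks <- split_blocks(gl)
  merged <- merge_blocks(blocks$chemicals, blocks$metabolites)
  report <- structure(list(removed_molecules = filt$report,
                           imputed_cell_count = imp$report$imputed_cell_count,
                           fallback_cells = imp$report$fallback_cells,
                           normalization_mode = "per-sample sum, per class block",
                           glog_offset = attr(gl, "glog_offset"),
                           max_missing_fraction = max_missing_fraction,
                           k = k),
                      class = "preprocess_report")
  list(table = merged, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocessing report\n")
  cat("  molecules removed (>", x$max_missing_fraction * 100, "% missing): ",
      nrow(x$removed_molecules), "\n", sep = "")
  cat("  cells imputed (k=", x$k, "): ", x$imputed_cell_count, "\n", sep = "")
  cat("  normalization: ", x$normalization_mode, "\n", sep = "")
  cat("  glog offsets: ",
      paste(names(x$glog_offset), signif(x$glog_offset, 4), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a preprocessing report as structured text
#'
#' Writes key/value lines followed by the removals table.
#'
#' @param report a `preprocess_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  stopifnot(inherits(report, "preprocess_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("max_missing_fraction: ", report$max_missing_fraction),
               paste0("k: ", report$k),
               paste0("imputed_cell_count: ", report$imputed_cell_count),
               paste0("normalization_mode: ", report$normalization_mode),
               paste0("glog_offset: ",
                      paste(names(report$glog_offset),
                            format(report$glog_offset, digits = 15),
                            sep = "=", collapse = ",")),
               paste0("removed_molecule_count: ",
                      nrow(report$removed_molecules)),
               "removed_molecules:"), con)
  if (nrow(report$removed_molecules))
    utils::write.table(report$removed_molecules, con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
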