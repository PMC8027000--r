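#' Annotated feature table
#'
#' Container for a samples x molecules intensity matrix together with
#' per-molecule annotations. This is the object that flows through the
#' preprocessing chain and into [fit_ggm()].
#'
#' @param intensities numeric matrix, samples in rows, molecules in columns.
#'   Missing cells are `NA`; present cells must be nonnegative. Row names are
#'   sample ids, column names molecule ids (supplied separately if absent).
#' @param molecules data frame with one row per column of `intensities` and
#'   columns `molecule_id`, `name`, `class` (`"chemical"` or `"metabolite"`),
#'   `msi_level` (1, 2 or 3) and optionally `block` (pathway-block id).
#' @param sample_ids optional character vector of sample ids, used when
#'   `intensities` has no row names.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `intensities` (named matrix) and `molecules` (annotation data frame).
#' @export
feature_table <- function(intensities, molecules, sample_ids = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (!is.null(sample_ids)) rownames(intensities) <- sample_ids
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("S%03d", seq_len(nrow(intensities)))
  molecules <- as.data.frame(molecules, stringsAsFactors = FALSE)
  required <- c("molecule_id", "name", "class", "msi_level")
  missing_cols <- setdiff(required, names(molecules))
  if (length(missing_cols))
    stop("molecule annotations lack column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"block" %in% names(molecules)) molecules$block <- NA_character_
  molecules$molecule_id <- as.character(molecules$molecule_id)
  if (nrow(molecules) != ncol(intensities))
    stop("annotation rows (", nrow(molecules), ") != intensity columns (",
         ncol(intensities), ")")
  colnames(intensities) <- molecules$molecule_id
  ft <- structure(list(intensities = intensities, molecules = molecules),
                  class = "feature_table")
  validate_feature_table(ft)
  ft
}

validate_feature_table <- function(ft) {
  x <- ft$intensities
  mol <- ft$molecules
  if (anyDuplicated(mol$molecule_id))
    stop("molecule ids are not unique")
  if (anyDuplicated(rownames(x)))
    stop("sample ids are not unique")
  bad <- !mol$class %in% c("chemical", "metabolite")
  if (any(bad))
    stop("unknown molecule class for: ",
         paste(mol$molecule_id[bad], collapse = ", "),
         " (must be 'chemical' or 'metabolite')")
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  n_miss <- sum(is.na(x$intensities))
  cls <- table(factor(x$molecules$class, c("chemical", "metabolite")))
  cat("feature_table: ", nrow(x$intensities), " samples x ",
      ncol(x$intensities), " molecules (", cls[["chemical"]], " chemicals, ",
      cls[["metabolite"]], " metabolites)\n", sep = "")
  cat("missing cells: ", n_miss, " (",
      round(100 * n_miss / length(x$intensities), 1), "%)\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Subset a feature table
#'
#' @param x a `feature_table`.
#' @param samples row (sample) selector: indices, logicals, or sample ids.
#' @param molecules column (molecule) selector: indices, logicals, or ids.
#' @return A `feature_table` restricted to the selection.
#' @export
subset_table <- function(x, samples = NULL, molecules = NULL) {
  stopifnot(inherits(x, "feature_table"))
  ints <- x$intensities
  mol <- x$molecules
  if (!is.null(samples)) ints <- ints[samples, , drop = FALSE]
  if (!is.null(molecules)) {
    if (is.character(molecules))
      molecules <- match(molecules, mol$molecule_id)
    ints <- ints[, molecules, drop = FALSE]
    mol <- mol[molecules, , drop = FALSE]
    rownames(mol) <- NULL
  }
  feature_table(ints, mol)
}

#' Read / write a feature table as delimited text
#'
#' The on-disk format is a pair of tab-separated files: the intensity matrix
#' (samples in rows, first column `sample_id`, empty cell = missing) and an
#' annotation sidecar with columns `molecule_id`, `name`, `class`,
#' `msi_level`, `block`.
#'
#' @param ft a `feature_table`.
#' @param path path of the intensity file; the sidecar path defaults to
#'   `path` with a `.molecules.tsv` suffix.
#' @param annotation_path path of the annotation sidecar.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(ft, path,
                                annotation_path = default_sidecar(path)) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(sample_id = rownames(ft$intensities),
                   as.data.frame(ft$intensities), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  utils::write.table(ft$molecules, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path,
                               annotation_path = default_sidecar(path)) {
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA"))
  mol <- utils::read.delim(annotation_path, check.names = FALSE,
                           na.strings = c("", "NA"),
                           colClasses = c(molecule_id = "character"))
  ints <- as.matrix(df[, -1, drop = FALSE])
  rownames(ints) <- as.character(df[[1]])
  feature_table(ints, mol)
}

default_sidecar <- function(path) {
  paste0(sub("\\.[^.]+$", "", path), ".molecules.tsv")
}
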