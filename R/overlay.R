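#' Read a reference reaction set
#'
#' Reads a delimited list of known biochemical reactions (columns
#' `molecule_a`, `molecule_b`, optional `label` with the regulating
#' gene/enzyme) into a `reference_reactions` object. Pairs are undirected and
#' deduplicated. A small curated fixture covering the polyunsaturated
#' fatty-acid elongation/desaturation chain and primary/secondary bile-acid
#' biosynthesis ships with the package, see the example.
#'
#' @param path delimited text file (tab- or comma-separated, autodetected).
#' @param source free-text provenance stored on the object.
#' @return An object of class `reference_reactions`: data frame of unique
#'   undirected pairs with `source` attribute.
#' @examples
#' ref <- read_reference_reactions(
#'   system.file("extdata", "reference_reactions.tsv", package = "exposonet"))
#' nrow(ref)
#' @export
read_reference_reactions <- function(path, source = path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "#")
  reference_reactions(df, source = source)
}

#' @rdname read_reference_reactions
#' @param reactions data frame with columns `molecule_a`, `molecule_b` and
#'   optionally `label`.
#' @export
reference_reactions <- function(reactions, source = "user") {
  df <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!all(c("molecule_a", "molecule_b") %in% names(df)))
    stop("reference reactions need columns 'molecule_a' and 'molecule_b'")
  if (!"label" %in% names(df)) df$label <- NA_character_
  a <- df$molecule_a; b <- df$molecule_b
  swap <- tolower(a) > tolower(b)
  df$molecule_a[swap] <- b[swap]; df$molecule_b[swap] <- a[swap]
  if (any(df$molecule_a == df$molecule_b))
    stop("self-reactions are not allowed")
  df <- df[!duplicated(tolower(paste(df$molecule_a, df$molecule_b,
                                     sep = "\r"))), , drop = FALSE]
  rownames(df) <- NULL
  structure(df[, c("molecule_a", "molecule_b", "label")],
            source = source, class = c("reference_reactions", "data.frame"))
}

# case-insensitive canonical pair key
pair_key <- function(a, b) {
  a <- tolower(a); b <- tolower(b)
  ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

#' Overlay a network on known biochemical reactions
#'
#' Compares the inferred edge set against a curated reference of known
#' reactions (case-insensitive exact name match, optionally through a
#' synonym map). Reports matched edges, inferred-only edges, reference-only
#' edges, and precision/recall of the inferred network with respect to the
#' reference: precision is the fraction of inferred edges that are known
#' reactions, recall the fraction of resolvable reference reactions that
#' were inferred. Reference names that do not resolve onto the network are
#' reported, never silently dropped.
#'
#' @param network an `exposure_network`; reference names are matched against
#'   both node `name` and `molecule_id`.
#' @param reference a `reference_reactions` object.
#' @param synonyms optional named character vector mapping reference names to
#'   network names.
#' @return An object of class `overlay_report`: list with `matched_edges`,
#'   `inferred_only`, `reference_only` (data frames),
#'   `precision_vs_reference`, `recall_of_reference` and
#'   `unresolved_names`.
#' @export
overlay_reference <- function(network, reference, synonyms = NULL) {
  stopifnot(inherits(network, "exposure_network"),
            inherits(reference, "reference_reactions"))
  ref <- reference
  if (!is.null(synonyms)) {
    map <- function(v) ifelse(v %in% names(synonyms), synonyms[v], v)
    ref$molecule_a <- map(ref$molecule_a)
    ref$molecule_b <- map(ref$molecule_b)
  }
  # resolve reference names to network molecule ids (name or id match)
  lut <- c(stats::setNames(network$nodes$molecule_id,
                           tolower(network$nodes$name)),
           stats::setNames(network$nodes$molecule_id,
                           tolower(network$nodes$molecule_id)))
  ra <- lut[tolower(ref$molecule_a)]
  rb <- lut[tolower(ref$molecule_b)]
  unresolved <- sort(unique(c(ref$molecule_a[is.na(ra)],
                              ref$molecule_b[is.na(rb)])))
  resolvable <- !is.na(ra) & !is.na(rb)
  if (!nrow(ref) || !any(resolvable))
    stop("no reference reaction resolves onto the network; unmatched names: ",
         if (length(unresolved)) paste(unresolved, collapse = ", ")
         else "(reference is empty)")
  ref_pairs <- unique(pair_key(ra[resolvable], rb[resolvable]))
  # all inferred edges compete; reference pairs count only when both
  # endpoints resolve onto the network's molecules
  inf <- network$edges
  inf_pairs <- pair_key(inf$a, inf$b)
  matched <- inf[inf_pairs %in% ref_pairs, , drop = FALSE]
  inferred_only <- inf[!inf_pairs %in% ref_pairs, , drop = FALSE]
  ref_res <- ref[resolvable, , drop = FALSE]
  ref_res$id_a <- ra[resolvable]; ref_res$id_b <- rb[resolvable]
  ref_keys <- pair_key(ref_res$id_a, ref_res$id_b)
  reference_only <- ref_res[!ref_keys %in% inf_pairs, , drop = FALSE]
  precision <- if (nrow(inf) == 0) {
    warning("network has no inferred edges; precision 0/0 reported as 0")
    0
  } else nrow(matched) / nrow(inf)
  recall <- nrow(matched) / length(ref_pairs)
  structure(list(matched_edges = matched,
                 inferred_only = inferred_only,
                 reference_only = reference_only,
                 precision_vs_reference = precision,
                 recall_of_reference = recall,
                 unresolved_names = unresolved,
                 reference_source = attr(reference, "source")),
            class = "overlay_report")
}

#' @export
print.overlay_report <- function(x, ...) {
  cat("overlay against known reactions (", x$reference_source, ")\n",
      sep = "")
  cat("  matched edges: ", nrow(x$matched_edges),
      "   inferred-only: ", nrow(x$inferred_only),
      "   reference-only: ", nrow(x$reference_only), "\n", sep = "")
  cat("  precision vs reference: ", signif(x$precision_vs_reference, 4),
      "   recall of reference: ", signif(x$recall_of_reference, 4), "\n",
      sep = "")
  if (length(x$unresolved_names))
    cat("  unresolved reference names: ",
        paste(x$unresolved_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write an overlay report as structured text
#'
#' @param report an `overlay_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_overlay_report <- function(report, path) {
  stopifnot(inherits(report, "overlay_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("reference_source: ", report$reference_source),
               paste0("precision_vs_reference: ",
                      format(report$precision_vs_reference, digits = 15)),
               paste0("recall_of_reference: ",
                      format(report$recall_of_reference, digits = 15)),
               paste0("unresolved_names: ",
                      paste(report$unresolved_names, collapse = ","))), con)
  for (part in c("matched_edges", "inferred_only", "reference_only")) {
    writeLines(paste0(part, ":"), con)
    if (nrow(report[[part]]))
      utils::write.table(format_edge_df(report[[part]]), con, sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a merged overlay network as GraphML
#'
#' Merges inferred and reference edges into one graph whose edges carry a
#' `status` attribute in `{matched, inferred_only, reference_only}`, the
#' usual black/red known-vs-inferred colouring when styled in a viewer.
#'
#' @param network an `exposure_network`.
#' @param report the matching `overlay_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_overlay_graphml <- function(network, report, path) {
  ed <- rbind(
    if (nrow(report$matched_edges))
      data.frame(a = report$matched_edges$a, b = report$matched_edges$b,
                 status = "matched", stringsAsFactors = FALSE),
    if (nrow(report$inferred_only))
      data.frame(a = report$inferred_only$a, b = report$inferred_only$b,
                 status = "inferred_only", stringsAsFactors = FALSE),
    if (nrow(report$reference_only))
      data.frame(a = report$reference_only$id_a,
                 b = report$reference_only$id_b,
                 status = "reference_only", stringsAsFactors = FALSE))
  vids <- sort(unique(c(ed$a, ed$b)))
  nodes <- network$nodes[match(vids, network$nodes$molecule_id), , drop = FALSE]
  nodes$molecule_id <- vids
  nodes$name[is.na(nodes$name)] <- vids[is.na(nodes$name)]
  nodes$class[is.na(nodes$class)] <- "metabolite"
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(
                                       name = nodes$molecule_id,
                                       label = nodes$name,
                                       class = nodes$class,
                                       stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Score edge recovery against synthetic ground truth
#'
#' Compares a network's inferred adjacency with the true adjacency of a
#' synthetic `ground_truth` model over all unique molecule pairs, reporting
#' sensitivity (recall of true edges), precision (1 - false discovery
#' proportion) and the Matthews correlation coefficient.
#'
#' @param network an `exposure_network` (its node set may be a subset of the
#'   truth's molecules; isolated molecules are accounted via provenance).
#' @param truth a `ground_truth` model from [make_ground_truth()].
#' @return list with `sensitivity`, `precision`, `mcc` and the confusion
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_recovery <- function(network, truth) {
  stopifnot(inherits(network, "exposure_network"),
            inherits(truth, "ground_truth"))
  ids <- truth$molecule_ids
  known <- unique(c(network$nodes$molecule_id, network$provenance$isolated))
  if (!all(known %in% ids))
    stop("network contains molecule ids absent from the ground truth: ",
         paste(setdiff(known, ids), collapse = ", "))
  p <- length(ids)
  idx <- stats::setNames(seq_len(p), ids)
  inferred <- matrix(0L, p, p)
  if (nrow(network$edges)) {
    ia <- idx[network$edges$a]; ib <- idx[network$edges$b]
    inferred[cbind(ia, ib)] <- 1L
    inferred[cbind(ib, ia)] <- 1L
  }
  ut <- upper.tri(inferred)
  inf <- inferred[ut] == 1
  tru <- truth$adjacency[ut] == 1
  tp <- sum(inf & tru); fp <- sum(inf & !tru)
  fn <- sum(!inf & tru); tn <- sum(!inf & !tru)
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(sensitivity = sens, precision = prec, mcc = mcc,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
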