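#' Build the typed exposure-metabolite network
#'
#' Turns the significant partial correlations of a fitted model into an
#' undirected typed graph: one node per molecule participating in at least
#' one significant edge (chemical or metabolite, carrying its MSI level), one
#' edge per significant pair carrying the signed partial correlation and its
#' p-value. Molecules without any significant edge are excluded from the
#' drawn graph but listed in the provenance so downstream accounting keeps
#' the full molecule set.
#'
#' @param fit a [fit_ggm()] result.
#' @param table optional [feature_table()] supplying molecule annotations;
#'   defaults to the annotations stored in the fit. Molecule ids must match.
#' @param cohort free-text cohort label stored in the provenance.
#' @return An object of class `exposure_network`: list with `nodes` (data
#'   frame: molecule_id, name, class, msi_level), `edges` (data frame: a, b,
#'   pcor, pvalue, sign) and `provenance` (cohort, fdr_threshold,
#'   pvalue_cutoff, isolated molecule ids).
#' @export
build_network <- function(fit, table = NULL, cohort = "cohort") {
  stopifnot(inherits(fit, "ggm"))
  molecules <- if (!is.null(table)) {
    stopifnot(inherits(table, "feature_table"))
    table$molecules
  } else fit$molecules
  ids <- colnames(fit$pcor)
  if (is.null(molecules)) {
    molecules <- data.frame(molecule_id = ids, name = ids,
                            class = "metabolite", msi_level = NA_integer_,
                            stringsAsFactors = FALSE)
  }
  if (!setequal(molecules$molecule_id, ids) ||
      length(molecules$molecule_id) != length(ids))
    stop("molecule ids of the fit and the table do not match")
  molecules <- molecules[match(ids, molecules$molecule_id), , drop = FALSE]
  et <- edge_table(fit, significant_only = TRUE)
  edges <- data.frame(a = et$molecule_a, b = et$molecule_b,
                      pcor = et$pcor, pvalue = et$pvalue,
                      sign = ifelse(et$pcor >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  connected <- unique(c(edges$a, edges$b))
  nodes <- molecules[molecules$molecule_id %in% connected,
                     c("molecule_id", "name", "class", "msi_level")]
  nodes <- nodes[order(nodes$molecule_id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 provenance = list(cohort = cohort,
                                   fdr_threshold = fit$fdr_threshold,
                                   pvalue_cutoff = fit$pvalue_cutoff,
                                   isolated = setdiff(ids, connected))),
            class = "exposure_network")
}

#' Construct an exposure network from explicit node and edge tables
#'
#' Low-level constructor used by the readers and tests.
#'
#' @param nodes data frame with `molecule_id`, `name`, `class`, `msi_level`.
#' @param edges data frame with `a`, `b`, `pcor`, `pvalue` (and optionally
#'   `sign`, recomputed from `pcor` if absent).
#' @param provenance list of provenance fields.
#' @return An `exposure_network`.
#' @export
exposure_network <- function(nodes, edges, provenance = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    swap <- edges$a > edges$b
    tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
    if (any(edges$a == edges$b)) stop("self-edges are not allowed")
    edges$sign <- ifelse(edges$pcor >= 0, "positive", "negative")
    missing_nodes <- setdiff(c(edges$a, edges$b), nodes$molecule_id)
    if (length(missing_nodes))
      stop("edge endpoints missing from nodes: ",
           paste(missing_nodes, collapse = ", "))
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  }
  nodes <- nodes[order(nodes$molecule_id), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "exposure_network")
}

#' @export
print.exposure_network <- function(x, ...) {
  cat("exposure_network: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges", sep = "")
  if (!is.null(x$provenance$cohort))
    cat(" (cohort: ", x$provenance$cohort, ")", sep = "")
  cat("\n")
  if (nrow(x$nodes)) {
    cls <- table(factor(x$nodes$class, c("chemical", "metabolite")))
    cat("  nodes: ", cls[["chemical"]], " chemicals, ", cls[["metabolite"]],
        " metabolites\n", sep = "")
  }
  if (nrow(x$edges)) {
    counts <- classify_edges(x)
    cat("  edges: ", paste(names(counts), counts, sep = "=",
                           collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Count edges by endpoint category
#'
#' Partitions the network's edges into metabolite-metabolite,
#' chemical-metabolite and chemical-chemical associations.
#'
#' @param network an `exposure_network`.
#' @return Named integer vector (`metabolite-metabolite`,
#'   `chemical-metabolite`, `chemical-chemical`); sums to the edge count.
#' @export
classify_edges <- function(network) {
  stopifnot(inherits(network, "exposure_network"))
  out <- c("metabolite-metabolite" = 0L, "chemical-metabolite" = 0L,
           "chemical-chemical" = 0L)
  if (!nrow(network$edges)) return(out)
  cls <- stats::setNames(network$nodes$class, network$nodes$molecule_id)
  ca <- cls[network$edges$a]; cb <- cls[network$edges$b]
  n_chem <- (ca == "chemical") + (cb == "chemical")
  out["metabolite-metabolite"] <- sum(n_chem == 0)
  out["chemical-metabolite"] <- sum(n_chem == 1)
  out["chemical-chemical"] <- sum(n_chem == 2)
  out
}

as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    if (nrow(network$edges)) network$edges else
      data.frame(a = character(), b = character()),
    directed = FALSE,
    vertices = data.frame(name = network$nodes$molecule_id,
                          label = network$nodes$name,
                          class = network$nodes$class,
                          msi_level = network$nodes$msi_level,
                          stringsAsFactors = FALSE))
  g
}

#' Extract a neighbourhood sub-network
#'
#' Induced subgraph on every node within `radius` hops of any seed molecule,
#' e.g. the immediate partners of a chemical of interest (radius 1) or its
#' wider pathway context.
#'
#' @param network an `exposure_network`.
#' @param seeds molecule ids present in the network.
#' @param radius hop count (>= 0).
#' @return An `exposure_network`; provenance records the seeds and radius.
#' @export
extract_subnetwork <- function(network, seeds, radius = 1) {
  stopifnot(inherits(network, "exposure_network"))
  unknown <- setdiff(seeds, network$nodes$molecule_id)
  if (length(unknown))
    stop("seed molecule(s) not in network: ", paste(unknown, collapse = ", "))
  if (radius < 0) stop("'radius' must be >= 0")
  g <- as_igraph(network)
  keep <- unique(names(unlist(igraph::ego(g, order = radius, nodes = seeds))))
  nodes <- network$nodes[network$nodes$molecule_id %in% keep, , drop = FALSE]
  edges <- network$edges[network$edges$a %in% keep &
                           network$edges$b %in% keep, , drop = FALSE]
  prov <- network$provenance
  prov$seeds <- seeds
  prov$radius <- radius
  exposure_network(nodes, edges, prov)
}

#' @rdname edge_table
#' @export
edge_table.exposure_network <- function(x, ...) {
  data.frame(molecule_a = x$edges$a, molecule_b = x$edges$b,
             pcor = x$edges$pcor, pvalue = x$edges$pvalue,
             significant = rep(TRUE, nrow(x$edges)),
             stringsAsFactors = FALSE)
}

#' Export a network as GraphML or SIF
#'
#' GraphML carries the node attributes (`class`, `msi_level`) and edge
#' attributes (`pcor`, `pvalue`, `sign`), so files open directly in standard
#' graph viewers with negative edges distinguishable. SIF is the minimal
#' Cytoscape interaction format: `a <sign> b` per line.
#'
#' @param network an `exposure_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "exposure_network"))
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(molecule_id = igraph::V(g)$name,
                      name = igraph::V(g)$label,
                      class = igraph::V(g)$class,
                      msi_level = igraph::V(g)$msi_level,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(a = el[, 1], b = el[, 2],
                      pcor = if (igraph::ecount(g)) igraph::E(g)$pcor
                             else numeric(),
                      pvalue = if (igraph::ecount(g)) igraph::E(g)$pvalue
                               else numeric(),
                      stringsAsFactors = FALSE)
  exposure_network(nodes, edges)
}

#' @rdname write_graphml
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "exposure_network"))
  lines <- if (nrow(network$edges))
    paste(network$edges$a, network$edges$sign, network$edges$b)
  else character()
  writeLines(lines, path)
  invisible(path)
}

#' Plot a fitted model's significant-edge network
#'
#' Renders the exposure network with metabolites and chemicals in different
#' colours, solid edges for positive and dashed edges for negative partial
#' correlations, edge width proportional to |pcor|.
#'
#' @param x a `ggm` fit.
#' @param ... passed to [igraph::plot.igraph()].
#' @return The plotted `exposure_network`, invisibly.
#' @export
plot.ggm <- function(x, ...) {
  net <- build_network(x)
  plot(net, ...)
  invisible(net)
}

#' @export
plot.exposure_network <- function(x, ...) {
  g <- as_igraph(x)
  if (igraph::vcount(g) == 0) {
    graphics::plot.new()
    graphics::title("empty network")
    return(invisible(x))
  }
  vcol <- ifelse(igraph::V(g)$class == "chemical", "#d73027", "#4575b4")
  elty <- ifelse(igraph::E(g)$sign == "negative", 2, 1)
  ew <- if (igraph::ecount(g)) 1 + 8 * abs(igraph::E(g)$pcor) else NULL
  igraph::plot.igraph(g, vertex.color = vcol, vertex.label.cex = 0.7,
                      edge.lty = elty, edge.width = ew, ...)
  invisible(x)
}
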