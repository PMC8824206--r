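# Sequence similarity networks and subfamily calling.
#
# Nodes are proteins, edges are pairwise search hits below an E-value
# cutoff; clusters of at least `min_size` well-connected sequences within a
# family are called subfamilies.

#' Load similarity edges from a tabular pairwise search file
#'
#' Accepts either a headered table with columns `query`, `subject`, `evalue`
#' or a headerless 12-column tabular search report (only columns 1, 2 and 11
#' are used). Self-hits are dropped and duplicate unordered pairs collapse
#' to their minimum E-value.
#'
#' @param path file path, or a data.frame with columns `query`, `subject`,
#'   `evalue`.
#' @return data.frame of edges `a`, `b` (sorted within pair), `evalue`.
#' @export
load_edges <- function(path) {
  if (is.data.frame(path)) {
    df <- path
    stopifnot(all(c("query", "subject", "evalue") %in% names(df)))
  } else {
    first <- readLines(path, n = 1, warn = FALSE)
    nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
    if (grepl("query", first, fixed = TRUE)) {
      df <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    } else if (nfield >= 12) {
      df <- utils::read.table(path, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
      df <- data.frame(query = as.character(df[[1]]),
                       subject = as.character(df[[2]]),
                       evalue = as.numeric(df[[11]]),
                       stringsAsFactors = FALSE)
    } else {
      df <- utils::read.table(path, sep = "\t", header = FALSE,
                              col.names = c("query", "subject", "evalue"),
                              stringsAsFactors = FALSE)
    }
  }
  df$evalue <- as.numeric(df$evalue)
  if (anyNA(df$evalue) || any(df$evalue < 0)) {
    stop("negative or unparseable E-value in similarity table")
  }
  df <- df[df$query != df$subject, , drop = FALSE]
  if (nrow(df) == 0) {
    return(data.frame(a = character(0), b = character(0), evalue = numeric(0),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(df$query, df$subject)
  b <- pmax(df$query, df$subject)
  key <- paste(a, b, sep = "\r")
  best <- tapply(df$evalue, key, min)
  pair <- strsplit(names(best), "\r", fixed = TRUE)
  out <- data.frame(a = vapply(pair, `[[`, character(1), 1),
                    b = vapply(pair, `[[`, character(1), 2),
                    evalue = as.numeric(best), stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a thresholded similarity network
#'
#' Keeps edges with E-value strictly below `cutoff`; every protein seen in
#' the input edge list remains a node, so proteins whose only hits fail the
#' cutoff become isolated nodes.
#'
#' @param edges data.frame from [load_edges()].
#' @param cutoff E-value threshold (> 0); the stringency knob that is tuned
#'   per family.
#' @return an `igraph` undirected graph with an `evalue` edge attribute.
#' @export
threshold_network <- function(edges, cutoff = 1e-5) {
  stopifnot(cutoff > 0)
  nodes <- sort(unique(c(edges$a, edges$b)))
  keep <- edges[edges$evalue < cutoff, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    keep[, c("a", "b", "evalue")], directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  g
}

#' Call subfamilies from a family similarity network
#'
#' In `component` mode (default) every connected component with at least
#' `min_size` nodes becomes a subfamily; `kcore` mode first restricts the
#' graph to its 2-core, discarding tree-like fringes, so "well-connected"
#' is read more strictly. Subfamilies are numbered by decreasing size, ties
#' broken by the lexicographically smallest member, so the labelling does
#' not depend on node input order. Remaining nodes are unclassified.
#'
#' @param graph igraph graph from [threshold_network()].
#' @param family_id family code used as the subfamily id prefix.
#' @param min_size minimum cluster size (default 10).
#' @param mode `"component"` or `"kcore"`.
#' @param seed_ids optional character vector of seed protein ids used to set
#'   `contains_seed`.
#' @return data.frame with `subfamily_id`, `size`, `contains_seed` and a
#'   list column `members`.
#' @export
call_subfamilies <- function(graph, family_id, min_size = 10,
                             mode = c("component", "kcore"),
                             seed_ids = character(0)) {
  mode <- match.arg(mode)
  stopifnot(min_size >= 2)
  g <- graph
  if (mode == "kcore") {
    core <- igraph::coreness(g)
    g <- igraph::induced_subgraph(g, names(core)[core >= 2])
  }
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- members[lengths(members) >= min_size]
  if (length(members) == 0) {
    out <- data.frame(subfamily_id = character(0), size = integer(0),
                      contains_seed = logical(0), stringsAsFactors = FALSE)
    out$members <- list()
    return(out)
  }
  smallest <- vapply(members, function(m) min(m), character(1))
  ord <- order(-lengths(members), smallest)
  members <- members[ord]
  out <- data.frame(
    subfamily_id = sprintf("%s_%d", family_id, seq_along(members)),
    size = lengths(members),
    contains_seed = vapply(members, function(m) any(m %in% seed_ids),
                           logical(1)),
    stringsAsFactors = FALSE
  )
  out$members <- lapply(members, sort)
  rownames(out) <- NULL
  out
}

#' Export a similarity network with subfamily annotations
#'
#' Writes GraphML (loadable by Cytoscape and other viewers) or an edge TSV
#' that round-trips through [load_edges()]. Node attributes carry the
#' subfamily assignment (`"unclassified"` for nodes outside subfamilies),
#' seed status, and an optional taxonomy label.
#'
#' @param graph igraph graph.
#' @param subfamilies data.frame from [call_subfamilies()] (may have 0 rows).
#' @param path output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @param seed_ids optional seed protein ids.
#' @param taxonomy optional named character vector protein -> taxon label.
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, subfamilies, path,
                           format = c("graphml", "edge_tsv"),
                           seed_ids = character(0), taxonomy = NULL) {
  format <- match.arg(format)
  nodes <- igraph::V(graph)$name
  assign <- rep("unclassified", length(nodes))
  names(assign) <- nodes
  for (i in seq_len(nrow(subfamilies))) {
    assign[subfamilies$members[[i]]] <- subfamilies$subfamily_id[i]
  }
  igraph::V(graph)$subfamily_id <- unname(assign[nodes])
  igraph::V(graph)$is_seed <- nodes %in% seed_ids
  if (!is.null(taxonomy)) {
    tax <- taxonomy[nodes]
    tax[is.na(tax)] <- ""
    igraph::V(graph)$taxonomy <- unname(tax)
  }
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(graph, what = "edges")
    out <- data.frame(query = ed$from, subject = ed$to, evalue = ed$evalue,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
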