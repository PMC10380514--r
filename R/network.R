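#' @title Protein-interaction network topology
#' @description Builds a simple undirected graph from score-filtered edges,
#'   extracts the main connected component, computes hub-style centralities
#'   (degree, harmonic closeness, ordered-pair betweenness, maximal clique
#'   centrality), ranks essential nodes, augments the network with newly
#'   prioritized TFs, and exports GraphML / edge-list representations.
#'
#'   Conventions follow the Cytoscape/cytoHubba tooling this mirrors:
#'   closeness is the harmonic form (sum of reciprocal distances, so values
#'   can exceed 1 and unreachable pairs contribute 0), betweenness counts
#'   ordered source-target pairs (twice the unordered value on undirected
#'   graphs), and MCC(v) is the sum over maximal cliques C containing v of
#'   (|C| - 1)!.
#' @name network_topology
NULL

#' Build an interaction graph from scored edges
#'
#' Edges are assumed pre-filtered by score threshold (see
#' [read_string_edges()]). Nodes are the endpoints of retained edges,
#' optionally intersected with a query set; query symbols with no retained
#' edge are reported separately, never added as isolated nodes.
#'
#' @param edges data.frame with columns `a`, `b`, `score`.
#' @param restrict_to optional character vector; only edges with both
#'   endpoints in this set are kept.
#' @return list of class `ppi_network`: `graph` (an igraph object with a
#'   `score` edge attribute), and `unconnected` (restrict_to symbols absent
#'   from the graph).
#' @export
build_graph <- function(edges, restrict_to = NULL) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    edges <- edges[edges$a != edges$b, , drop = FALSE]
    if (!is.null(restrict_to)) {
      restrict_to <- unique(restrict_to)
      edges <- edges[edges$a %in% restrict_to & edges$b %in% restrict_to, ,
                     drop = FALSE]
    }
  }
  if (nrow(edges) > 0) {
    # merge duplicate unordered pairs keeping the max score
    lo <- pmin(edges$a, edges$b); hi <- pmax(edges$a, edges$b)
    key <- paste(lo, hi, sep = "\r")
    sc <- tapply(edges$score, key, max)
    parts <- strsplit(names(sc), "\r", fixed = TRUE)
    edges <- data.frame(a = vapply(parts, `[`, character(1), 1L),
                        b = vapply(parts, `[`, character(1), 2L),
                        score = unname(sc), stringsAsFactors = FALSE)
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  }
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  unconnected <- if (is.null(restrict_to)) character(0) else
    sort(setdiff(restrict_to, igraph::V(g)$name))
  structure(list(graph = g, unconnected = unconnected),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d nodes, %d edges (%d query symbols unconnected)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$unconnected)))
  invisible(x)
}

as_igraph <- function(g) {
  if (inherits(g, "ppi_network")) g$graph else g
}

#' Extract the main connected component
#'
#' Returns the largest connected component; exact ties in size are broken by
#' the lexicographically smallest node-name set, so the choice is
#' deterministic.
#'
#' @param g an igraph object or `ppi_network`.
#' @return list: `graph` (main-component igraph), `excluded` (sorted symbols
#'   of all other nodes).
#' @export
main_component <- function(g) {
  g <- as_igraph(g)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie-break: lexicographically smallest sorted node-name vector
    keysets <- lapply(best, function(ci)
      sort(igraph::V(g)$name[comp$membership == ci]))
    keys <- vapply(keysets, paste, character(1), collapse = "\r")
    best <- best[order(keys)[1]]
  }
  keep <- igraph::V(g)[comp$membership == best]
  main <- igraph::induced_subgraph(g, keep)
  excluded <- sort(setdiff(igraph::V(g)$name, igraph::V(main)$name))
  list(graph = main, excluded = excluded)
}

#' Whole-graph topology statistics
#'
#' `avg_neighbors` is exactly 2E/N. The clustering coefficient defaults to
#' the mean of local coefficients with degree-<2 nodes contributing 0 (the
#' NetworkAnalyzer convention); global transitivity is available as an
#' alternative.
#'
#' @param g an igraph object or `ppi_network`.
#' @param clustering `"local"` (default) or `"global"`.
#' @return list of class `topology_stats`: n_nodes, n_edges,
#'   clustering_coefficient, avg_neighbors.
#' @export
topology_stats <- function(g, clustering = c("local", "global")) {
  clustering <- match.arg(clustering)
  g <- as_igraph(g)
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  if (n == 0) stop("empty graph", call. = FALSE)
  cc <- if (clustering == "local") {
    loc <- igraph::transitivity(g, type = "local", isolates = "zero")
    mean(loc)
  } else {
    tr <- igraph::transitivity(g, type = "global")
    if (is.nan(tr)) 0 else tr
  }
  structure(list(n_nodes = n, n_edges = e,
                 clustering_coefficient = cc,
                 avg_neighbors = 2 * e / n),
            class = "topology_stats")
}

#' @export
print.topology_stats <- function(x, ...) {
  cat(sprintf("%d nodes, %d edges; clustering coefficient %.3f; average neighbors %.3f\n",
              x$n_nodes, x$n_edges, x$clustering_coefficient,
              x$avg_neighbors))
  invisible(x)
}

#' Maximal clique centrality
#'
#' MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!.
#' For a node whose neighborhood contains no edge this equals its degree
#' (each incident edge is a maximal 2-clique). Cliques are enumerated
#' exactly; if their number exceeds `clique_budget` an explicit resource
#' error is raised rather than truncating silently.
#'
#' @param g an igraph object or `ppi_network`.
#' @param clique_budget maximum number of maximal cliques to enumerate.
#' @return named numeric vector of MCC scores.
#' @export
mcc_scores <- function(g, clique_budget = 1e5) {
  g <- as_igraph(g)
  n_cl <- igraph::count_max_cliques(g)
  if (n_cl > clique_budget)
    stop("maximal-clique enumeration budget exceeded (", n_cl, " > ",
         clique_budget, " cliques); raise clique_budget explicitly",
         call. = FALSE)
  cl <- igraph::max_cliques(g)
  mcc <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  for (cq in cl) {
    w <- factorial(length(cq) - 1)
    idx <- as.integer(cq)
    mcc[idx] <- mcc[idx] + w
  }
  mcc
}

#' Node centralities (degree, harmonic closeness, betweenness, MCC)
#'
#' Computed on the given graph (normally the main component). Betweenness
#' uses the ordered-pair convention (every ordered source-target pair s != t
#' counts, so values are twice igraph's undirected unordered-pair output).
#' Each metric also receives a dense rank (1 = best; equal values share a
#' rank, the next distinct value gets the next integer).
#'
#' @param g an igraph object or `ppi_network`.
#' @param clique_budget passed to [mcc_scores()].
#' @return data.frame of class `centrality_table`: node, degree, closeness,
#'   betweenness, mcc and the four `*_rank` columns.
#' @export
centralities <- function(g, clique_budget = 1e5) {
  g <- as_igraph(g)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  deg <- igraph::degree(g)
  clo <- igraph::harmonic_centrality(g, normalized = FALSE)
  btw <- 2 * igraph::betweenness(g, directed = FALSE)
  mcc <- mcc_scores(g, clique_budget = clique_budget)

  dense_rank <- function(x) match(x, sort(unique(x), decreasing = TRUE))
  out <- data.frame(node = igraph::V(g)$name,
                    degree = as.integer(deg),
                    closeness = as.numeric(clo),
                    betweenness = as.numeric(btw),
                    mcc = as.numeric(mcc),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$degree_rank <- dense_rank(out$degree)
  out$closeness_rank <- dense_rank(out$closeness)
  out$betweenness_rank <- dense_rank(out$betweenness)
  out$mcc_rank <- dense_rank(out$mcc)
  out <- out[order(out$mcc_rank, out$degree_rank, out$node), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("centrality_table", "data.frame"))
}

#' Essentiality ranking
#'
#' A node is essential iff it is dense-rank 1 on all four centralities
#' simultaneously. Also returns the top-k report per metric (report ordering
#' ties broken by MCC, then degree, then symbol).
#'
#' @param records a `centrality_table`.
#' @param top_k how many nodes to report per metric (default 3).
#' @return list of class `essentiality`: `table` (centrality table with an
#'   `essential` flag), `essential` (symbol vector), `top` (named list of
#'   top-k data.frames per metric), `split_first` (TRUE when no single node
#'   holds rank 1 on all metrics).
#' @export
rank_essential <- function(records, top_k = 3) {
  ess <- records$node[records$degree_rank == 1 & records$closeness_rank == 1 &
                        records$betweenness_rank == 1 & records$mcc_rank == 1]
  tab <- records
  tab$essential <- tab$node %in% ess
  ord <- order(-tab$mcc, -tab$degree, tab$node)
  top <- lapply(c(degree = "degree", closeness = "closeness",
                  betweenness = "betweenness", mcc = "mcc"), function(m) {
    o <- order(-tab[[m]], -tab$mcc, -tab$degree, tab$node)
    utils::head(tab[o, c("node", m)], top_k)
  })
  structure(list(table = tab[ord, , drop = FALSE],
                 essential = sort(ess),
                 top = top,
                 split_first = length(ess) == 0),
            class = "essentiality")
}

#' @export
print.essentiality <- function(x, ...) {
  if (length(x$essential) > 0) {
    cat("Essential node(s) (rank 1 on degree, closeness, betweenness, MCC):",
        paste(x$essential, collapse = ", "), "\n")
  } else {
    cat("No single node is first-ranked on all four centralities (split first ranks)\n")
  }
  for (m in names(x$top)) {
    t <- x$top[[m]]
    cat(sprintf("  top %s: %s\n", m,
                paste(sprintf("%s (%g)", t$node, t[[2]]), collapse = ", ")))
  }
  invisible(x)
}

#' Augment a network with newly prioritized nodes
#'
#' Rebuilds the graph from the union of the original restriction set and the
#' new symbols, using the supplied (already score-filtered) edges. New
#' symbols with no qualifying edge are reported as unconnected.
#'
#' @param g the original `ppi_network` (its node set is kept).
#' @param new_nodes character vector of symbols to add.
#' @param edges scored-edge data.frame covering old and new nodes.
#' @return a `ppi_network` with extra fields `joined` (new symbols present in
#'   the rebuilt graph) and `unconnected_new` (new symbols without edges).
#' @export
augment_network <- function(g, new_nodes, edges) {
  old_nodes <- igraph::V(as_igraph(g))$name
  new_nodes <- unique(new_nodes)
  allowed <- union(old_nodes, new_nodes)
  net <- build_graph(edges, restrict_to = allowed)
  present <- igraph::V(net$graph)$name
  net$joined <- sort(intersect(new_nodes, present))
  net$unconnected_new <- sort(setdiff(new_nodes, present))
  net
}

#' Export a graph with node attributes
#'
#' Writes GraphML (with centrality attributes and the visual size rule
#' size = 10 x MCC) or a plain scored edge list re-readable by
#' [read_string_edges()].
#'
#' @param g an igraph object or `ppi_network`.
#' @param centralities optional `centrality_table` whose metrics become node
#'   attributes.
#' @param path output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return the path, invisibly.
#' @export
export_graph <- function(g, centralities = NULL, path,
                         format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- as_igraph(g)
  if (!is.null(centralities)) {
    idx <- match(igraph::V(g)$name, centralities$node)
    for (m in c("degree", "closeness", "betweenness", "mcc")) {
      g <- igraph::set_vertex_attr(g, m, value = centralities[[m]][idx])
    }
    g <- igraph::set_vertex_attr(g, "size",
                                 value = 10 * centralities$mcc[idx])
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    df <- igraph::as_data_frame(g, what = "edges")
    score <- if ("score" %in% names(df)) df$score else rep(1, nrow(df))
    write_string_edges(data.frame(a = df$from, b = df$to, score = score,
                                  stringsAsFactors = FALSE), path)
  }
  invisible(path)
}
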