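#' Filters applied before repertoire-graph construction
#'
#' Defaults reproduce the reference workflow: attractors with fewer than 10
#' member sequences are removed, edges between representatives farther than 8
#' (weighted scale) are removed, and only attractors active in more than 60%
#' of the time points are kept. The results are not strongly sensitive to
#' these values; they balance statistical support per node against graph
#' size.
#'
#' @param min_members Minimum number of member sequences per attractor.
#' @param max_edge_distance Maximum representative-to-representative distance
#'   for an edge.
#' @param min_timepoint_fraction An attractor must be active (amplitude > 0
#'   in at least one sample) in strictly more than this fraction of time
#'   points.
#' @return An object of class `graph_filters`.
#' @export
graph_filters <- function(min_members = 10, max_edge_distance = 8,
                          min_timepoint_fraction = 0.6) {
  if (min_members < 1 || max_edge_distance <= 0 ||
      min_timepoint_fraction <= 0 || min_timepoint_fraction > 1) {
    abort("invalid graph filters: all must be positive, fraction in (0, 1].")
  }
  structure(list(min_members = min_members,
                 max_edge_distance = max_edge_distance,
                 min_timepoint_fraction = min_timepoint_fraction),
            class = "graph_filters")
}

#' Select the attractors that enter the repertoire graphs
#'
#' Keeps an attractor iff (a) its size (number of member sequences) is at
#' least `min_members`, and (b) it is active — amplitude > 0 in at least one
#' sample — in strictly more than `min_timepoint_fraction` of the time
#' points present in `activity`. The time-point criterion is evaluated
#' globally (across all samples) before any per-sample graph is built, so
#' every graph draws nodes from one shared attractor set.
#'
#' @param aset A `ca_attractor_set`.
#' @param activity Activity tibble from [attractor_activity()].
#' @param filters A [graph_filters()] object.
#' @return Tibble `ca_id`, `representative`, `size`, `n_timepoints_active`
#'   of the retained attractors.
#' @export
filter_attractors <- function(aset, activity, filters = graph_filters()) {
  stopifnot(inherits(aset, "ca_attractor_set"))
  timepoints <- sort(unique(activity$time_point))
  n_tp <- length(timepoints)
  tp_active <- activity |>
    filter(.data$amplitude > 0) |>
    distinct(.data$ca_id, .data$time_point) |>
    count(.data$ca_id, name = "n_timepoints_active")
  kept <- aset$attractors |>
    left_join(tp_active, by = "ca_id") |>
    mutate(n_timepoints_active = dplyr::coalesce(.data$n_timepoints_active, 0L)) |>
    filter(.data$size >= filters$min_members,
           .data$n_timepoints_active > filters$min_timepoint_fraction * n_tp) |>
    select("ca_id", "representative", "size", "n_timepoints_active")
  if (nrow(kept) == 0) {
    warn("no attractors survive the graph filters")
  }
  kept
}

#' Build one repertoire graph for a (sample, time point)
#'
#' Nodes are the filtered attractors with positive amplitude at this (sample,
#' time point); an edge joins two nodes when the weighted edit distance
#' between their representatives is at most `filters$max_edge_distance`,
#' with the distance stored as the edge weight. Shortest-path statistics on
#' these graphs count edges (unweighted hops).
#'
#' @param kept Filtered attractor tibble from [filter_attractors()].
#' @param activity Activity tibble.
#' @param sample_id,time_point The (sample, time point) to build.
#' @param weights An [edit_weights()] object for the representative metric.
#' @param filters A [graph_filters()] object.
#' @param rep_dist Optional precomputed representative distance matrix
#'   (rownames/colnames = `ca_id`), as cached by [build_graphs()].
#' @return An `igraph` object with graph attributes `sample_id`,
#'   `time_point`; vertex attributes `name` (ca_id), `amplitude`, `size`;
#'   edge attribute `distance`.
#' @export
build_graph <- function(kept, activity, sample_id, time_point,
                        weights = edit_weights(), filters = graph_filters(),
                        rep_dist = NULL) {
  act <- activity[activity$sample_id == sample_id &
                    activity$time_point == time_point, ]
  nodes <- kept |>
    inner_join(filter(act, .data$amplitude > 0), by = "ca_id")
  if (is.null(rep_dist)) {
    rep_dist <- .rep_dist_matrix(kept, weights)
  }
  .graph_from_nodes(nodes, rep_dist, filters, sample_id, time_point)
}

.rep_dist_matrix <- function(kept, weights) {
  d <- .wl_cross(kept$representative, kept$representative, weights)
  dimnames(d) <- list(as.character(kept$ca_id), as.character(kept$ca_id))
  d
}

.graph_from_nodes <- function(nodes, rep_dist, filters, sample_id, time_point) {
  ids <- as.character(nodes$ca_id)
  n <- length(ids)
  if (n == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    d <- rep_dist[ids, ids, drop = FALSE]
    adj <- d <= filters$max_edge_distance + .wl_tol
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- ids
    igraph::V(g)$amplitude <- nodes$amplitude
    igraph::V(g)$size <- nodes$size
    if (igraph::ecount(g) > 0) {
      ends <- igraph::as_edgelist(g)
      igraph::E(g)$distance <- d[cbind(ends[, 1], ends[, 2])]
    }
  }
  g <- igraph::set_graph_attr(g, "sample_id", sample_id)
  igraph::set_graph_attr(g, "time_point", time_point)
}

#' Build the repertoire graph for every (sample, time point)
#'
#' Applies [filter_attractors()] once, caches the representative distance
#' matrix, and builds one graph per (sample, time point) column of the
#' activity matrix.
#'
#' @inheritParams filter_attractors
#' @param weights An [edit_weights()] object.
#' @return A tibble `sample_id`, `time_point`, `n_nodes`, `n_edges`,
#'   `graph` (list column of igraph objects), of class `ca_graph_set`.
#' @export
build_graphs <- function(aset, activity, weights = edit_weights(),
                         filters = graph_filters()) {
  kept <- filter_attractors(aset, activity, filters)
  rep_dist <- .rep_dist_matrix(kept, weights)
  cols <- distinct(activity, .data$sample_id, .data$time_point) |>
    arrange(.data$sample_id, .data$time_point)
  act_pos <- filter(activity, .data$amplitude > 0) |>
    inner_join(kept, by = "ca_id")
  graphs <- purrr::map2(cols$sample_id, cols$time_point, function(s, t) {
    nodes <- filter(act_pos, .data$sample_id == s, .data$time_point == t)
    .graph_from_nodes(nodes, rep_dist, filters, s, t)
  })
  out <- cols |>
    mutate(n_nodes = purrr::map_int(graphs, igraph::vcount),
           n_edges = purrr::map_int(graphs, igraph::ecount),
           graph = graphs)
  class(out) <- c("ca_graph_set", class(out))
  out
}

#' Molecular Topological Index of a repertoire graph
#'
#' The MTI of a graph with degree vector d, adjacency matrix A and
#' shortest-path edge-count matrix D is `sum_i sum_j d_i (A_ij + D_ij)`. It
#' decreases as a graph of fixed size becomes more branched/stretched, which
#' is what makes it discriminative for diluting repertoire networks. For a
#' disconnected graph the index is evaluated per connected component and
#' summed, so unreachable pairs contribute nothing and the definition
#' reduces to the classical one on connected graphs.
#'
#' @param g An igraph object (undirected).
#' @return A single non-negative number; 0 for an empty or edgeless graph.
#' @examples
#' mti(igraph::make_ring(3))
#' @export
mti <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0) return(0)
  comps <- igraph::components(g)
  total <- 0
  for (ci in seq_len(comps$no)) {
    vs <- which(comps$membership == ci)
    if (length(vs) < 2) next
    sub <- igraph::induced_subgraph(g, vs)
    A <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
    D <- igraph::distances(sub, weights = NA)
    d <- igraph::degree(sub)
    total <- total + sum(d * rowSums(A + D))
  }
  total
}

#' Betweenness centrality of every node (unnormalized)
#'
#' For node i, the sum over unordered pairs j != k (both different from i) of
#' the fraction of shortest j-k paths (counting edges) that pass through i.
#' No normalization is applied; pairs in different components contribute 0.
#'
#' @param g An igraph object.
#' @return Named numeric vector (names = node names).
#' @export
bwc <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0) return(setNames(numeric(0), character(0)))
  igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE)
}

#' Thresholded betweenness sum (sBWC) across a set of graphs
#'
#' Pools the betweenness values of every node of every graph, takes their
#' median as the global threshold `th50`, and reports per graph the sum of
#' its betweenness components strictly greater than `th50` — "the amount of
#' influential attractors" in that graph. Empty graphs contribute no values
#' to the pool and get sBWC 0. Any pooled quantile can be substituted for
#' the median via `probs` to check threshold insensitivity.
#'
#' @param graphs A `ca_graph_set` from [build_graphs()] (or any tibble with a
#'   `graph` list column).
#' @param probs Quantile used for the pooled threshold (default 0.5, the
#'   median).
#' @return A tibble `sample_id`, `time_point`, `sbwc`, with the threshold in
#'   attribute `th`.
#' @export
sbwc <- function(graphs, probs = 0.5) {
  stopifnot(is.data.frame(graphs), "graph" %in% names(graphs))
  bwc_list <- purrr::map(graphs$graph, bwc)
  pooled <- unlist(bwc_list, use.names = FALSE)
  th <- if (length(pooled) == 0) 0 else
    unname(stats::quantile(pooled, probs = probs, type = 7))
  out <- graphs |>
    select("sample_id", "time_point") |>
    mutate(sbwc = purrr::map_dbl(bwc_list, function(v) sum(v[v > th])))
  attr(out, "th") <- th
  out
}

#' Per-(sample, time point) graph measure table
#'
#' Computes MTI and sBWC for every graph.
#'
#' @inheritParams sbwc
#' @return A tibble `sample_id`, `time_point`, `n_nodes`, `n_edges`, `mti`,
#'   `sbwc`.
#' @export
measure_table <- function(graphs, probs = 0.5) {
  s <- sbwc(graphs, probs = probs)
  graphs |>
    select("sample_id", "time_point", "n_nodes", "n_edges") |>
    mutate(mti = purrr::map_dbl(graphs$graph, mti)) |>
    left_join(s, by = c("sample_id", "time_point"))
}

#' Per-sample summary of graph measures
#'
#' Median and standard deviation of each measure across a sample's own time
#' points, the per-sample view used to compare control and transgenic
#' groups.
#'
#' @param measures Output of [measure_table()].
#' @return A tibble with one row per sample: `sample_id`, `n_timepoints`,
#'   `mti_median`, `mti_sd`, `sbwc_median`, `sbwc_sd`.
#' @export
measure_summary <- function(measures) {
  if (any(table(measures$sample_id) == 1)) {
    warn("sample(s) with a single time point: standard deviation reported as 0")
  }
  measures |>
    group_by(.data$sample_id) |>
    summarise(
      n_timepoints = n(),
      mti_median = median(.data$mti),
      mti_sd = if (n() > 1) sd(.data$mti) else 0,
      sbwc_median = median(.data$sbwc),
      sbwc_sd = if (n() > 1) sd(.data$sbwc) else 0,
      .groups = "drop")
}

#' Export a repertoire graph for external tools
#'
#' Writes GraphML (via igraph) or GEXF (minimal writer) with node size
#' attribute = attractor size and edge weight = representative distance, so
#' the graphs open directly in Gephi-like tools.
#'
#' @param g An igraph repertoire graph from [build_graph()].
#' @param path Output path.
#' @param format `"graphml"` or `"gexf"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  stopifnot(igraph::is_igraph(g))
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    .write_gexf(g, path)
  }
  invisible(path)
}

.write_gexf <- function(g, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  ids <- if (igraph::vcount(g) > 0) igraph::V(g)$name else character(0)
  sizes <- if (igraph::vcount(g) > 0 &&
               !is.null(igraph::vertex_attr(g, "size")))
    igraph::V(g)$size else rep(1, length(ids))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://gexf.net/1.3" version="1.3">',
    '  <graph defaultedgetype="undirected">',
    '    <nodes>')
  if (length(ids) > 0) {
    lines <- c(lines, sprintf(
      '      <node id="%s" label="%s"><size value="%g"/></node>',
      esc(ids), esc(ids), sizes))
  }
  lines <- c(lines, "    </nodes>", "    <edges>")
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    wts <- igraph::edge_attr(g, "distance") %||% rep(1, nrow(el))
    lines <- c(lines, sprintf(
      '      <edge id="%d" source="%s" target="%s" weight="%g"/>',
      seq_len(nrow(el)), esc(el[, 1]), esc(el[, 2]), wts))
  }
  lines <- c(lines, "    </edges>", "  </graph>", "</gexf>")
  writeLines(lines, path)
  invisible(path)
}
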