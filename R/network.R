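# Spatial graph extraction: complete centroid graph, distance pruning,
# structural metrics (link density, components, clusters).

#' Construct a resource network
#'
#' A resource network holds a node table (waterholes) and an unordered set of
#' distance-weighted links. Isolated nodes remain members of the network:
#' they carry water area and habitat even when unreachable.
#'
#' @param nodes a [waterhole_table()].
#' @param links data.frame with columns `from`, `to` (waterhole ids),
#'   `length` (Euclidean centroid distance, m) and optionally `probability`.
#' @param threshold the movement-distance threshold (m) the links were pruned
#'   to, or `NULL` for an unthresholded network.
#' @return a `resource_network`.
#' @export
resource_network <- function(nodes, links, threshold = NULL) {
  if (is.null(links$probability)) links$probability <- rep(NA_real_, nrow(links))
  links <- as.data.frame(links)[, c("from", "to", "length", "probability")]
  links$from <- as.character(links$from); links$to <- as.character(links$to)
  if (nrow(links)) {
    if (any(links$from == links$to)) abort_validation("self-links are not allowed")
    if (!all(c(links$from, links$to) %in% nodes$id))
      abort_validation("link endpoint not present in node table")
    if (any(links$length < 0)) abort_validation("negative link length")
    key <- paste(pmin(links$from, links$to), pmax(links$from, links$to))
    if (anyDuplicated(key)) abort_validation("duplicate link between a node pair")
    if (!is.null(threshold) && any(links$length > threshold))
      abort_validation("link longer than the network threshold")
  }
  structure(list(nodes = nodes, links = links, threshold = threshold),
            class = "resource_network")
}

#' @export
print.resource_network <- function(x, ...) {
  cat(sprintf("Resource network: %d nodes, %d links", nrow(x$nodes), nrow(x$links)))
  if (!is.null(x$threshold)) cat(sprintf(", threshold %.0f m", x$threshold))
  cat("\n")
  invisible(x)
}

#' Build the complete centroid graph
#'
#' Links every pair of waterholes with a link whose length is the Euclidean
#' distance between their centroids: n(n-1)/2 links, no threshold.
#'
#' @param tab a [waterhole_table()] with at least one waterhole.
#' @return a [resource_network()].
#' @export
build_complete_network <- function(tab) {
  n <- nrow(tab)
  if (n < 1) abort_validation("cannot build a network from an empty table")
  if (n == 1) {
    return(resource_network(tab, data.frame(from = character(0), to = character(0),
                                            length = numeric(0))))
  }
  d <- stats::dist(cbind(tab$x, tab$y))
  ij <- utils::combn(n, 2)
  links <- data.frame(from = tab$id[ij[1, ]], to = tab$id[ij[2, ]],
                      length = as.numeric(d), stringsAsFactors = FALSE)
  resource_network(tab, links)
}

#' Prune links by a movement-distance threshold
#'
#' Keeps exactly the links whose length is less than or equal to `d_max`
#' (a link at exactly the threshold is within the species' movement ability
#' and is kept); nodes are unchanged.
#'
#' @param network a [resource_network()].
#' @param d_max maximum movement distance (m), > 0.
#' @return a [resource_network()] with `threshold = d_max`.
#' @export
prune_by_distance <- function(network, d_max) {
  if (!is.finite(d_max) || d_max <= 0) abort_validation("d_max must be > 0")
  resource_network(network$nodes,
                   network$links[network$links$length <= d_max, , drop = FALSE],
                   threshold = d_max)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$links[, c("from", "to", "length", "probability")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes$id, stringsAsFactors = FALSE)
  )
}

#' Structural metrics of a resource network
#'
#' Link density `L` is the proportion of realized links out of the
#' n(n-1)/2 links of the complete graph on the same nodes (`L = 0` for a
#' single node). Components are maximal link-connected node sets; clusters
#' are components with at least two nodes, matching the convention of
#' counting linked waterhole groups separately from isolated waterholes.
#'
#' @param network a [resource_network()].
#' @return a `network_metrics` list: `n_nodes`, `total_water_area` (m2),
#'   `n_links`, `link_density`, `component_sizes`, `n_clusters`, `n_isolates`,
#'   and the per-node component `membership`.
#' @export
compute_metrics <- function(network) {
  n <- nrow(network$nodes)
  m <- nrow(network$links)
  L <- if (n >= 2) m / (n * (n - 1) / 2) else 0
  comp <- igraph::components(as_igraph(network))
  sizes <- as.integer(comp$csize)
  structure(list(
    n_nodes = n,
    total_water_area = sum(network$nodes$area_m2),
    n_links = m,
    link_density = L,
    component_sizes = sizes,
    n_clusters = sum(sizes >= 2),
    n_isolates = sum(sizes == 1),
    membership = stats::setNames(as.integer(comp$membership),
                                 names(comp$membership))
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0("Network metrics: %d nodes, %d links (L = %.4f), ",
                     "%d cluster(s), %d isolate(s), water area %.3f km2\n"),
              x$n_nodes, x$n_links, x$link_density, x$n_clusters,
              x$n_isolates, x$total_water_area / 1e6))
  invisible(x)
}
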