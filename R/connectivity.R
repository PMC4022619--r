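# Dispersal kernel, maximum-product path probabilities, PC numerator,
# and patch-removal node importance (dPC).

#' Calibrate a negative exponential dispersal kernel
#'
#' The kernel `p(d) = exp(-k d)` is calibrated so that the probability of a
#' movement exceeding the species' maximum movement distance `d_max` equals
#' `tail_prob`: `k = -ln(tail_prob) / d_max`, hence `p(0) = 1` and
#' `p(d_max) = tail_prob`.
#'
#' @param d_max maximum movement distance (m), > 0.
#' @param tail_prob probability of moving beyond `d_max` (default 0.05).
#' @return a `dispersal_kernel` with elements `d_max`, `tail_prob`, `k`
#'   (per metre) and the probability function `p`.
#' @export
calibrate_kernel <- function(d_max, tail_prob = 0.05) {
  if (!is.finite(d_max) || d_max <= 0) abort_validation("d_max must be > 0")
  if (!is.finite(tail_prob) || tail_prob <= 0 || tail_prob >= 1)
    abort_validation("tail_prob must be in (0, 1)")
  k <- -log(tail_prob) / d_max
  structure(list(d_max = d_max, tail_prob = tail_prob, k = k,
                 p = function(d) exp(-k * d)),
            class = "dispersal_kernel")
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat(sprintf("Negative exponential dispersal kernel: d_max = %.0f m, p(d_max) = %.3g, k = %.6g /m\n",
              x$d_max, x$tail_prob, x$k))
  invisible(x)
}

#' Assign dispersal probabilities to links
#'
#' Sets each link's `probability` to `exp(-k * length)`. The network must
#' already be pruned to the kernel's `d_max`, so probabilities fall in
#' `[tail_prob, 1]`.
#'
#' @param network a [resource_network()] with all link lengths `<= d_max`.
#' @param kernel a [calibrate_kernel()] result.
#' @return the network with link probabilities filled in.
#' @export
assign_link_probabilities <- function(network, kernel) {
  if (nrow(network$links) && any(network$links$length > kernel$d_max))
    abort_validation("network contains links longer than the kernel's d_max; prune first")
  network$links$probability <- exp(-kernel$k * network$links$length)
  network
}

#' Maximum-product pairwise connection probabilities
#'
#' For every node pair, the maximum over all paths of the product of link
#' dispersal probabilities, computed as shortest paths on `-log(p)` weights.
#' Disconnected pairs get 0; the diagonal is 1. With
#' `mode = "component"` the max-product machinery is replaced by a component
#' indicator (`p* = 1` whenever two nodes share a component), a coarser
#' variant offered for sensitivity comparisons.
#'
#' @param network a [resource_network()] with link probabilities assigned,
#'   all in (0, 1].
#' @param mode `"max_product"` (default) or `"component"`.
#' @return symmetric numeric matrix with node ids as dimnames.
#' @export
max_product_paths <- function(network, mode = c("max_product", "component")) {
  mode <- match.arg(mode)
  ids <- network$nodes$id
  pr <- network$links$probability
  if (nrow(network$links)) {
    if (any(is.na(pr))) abort_validation("link probabilities not assigned")
    if (any(pr <= 0) || any(pr > 1)) abort_validation("link probabilities must be in (0, 1]")
  }
  g <- as_igraph(network)
  if (mode == "component") {
    memb <- igraph::components(g)$membership
    pmat <- outer(memb, memb, "==") * 1
  } else {
    w <- -log(igraph::E(g)$probability)
    d <- igraph::distances(g, weights = w)
    pmat <- exp(-d)      # Inf distances (disconnected) -> 0
    diag(pmat) <- 1
  }
  pmat <- pmat[ids, ids, drop = FALSE]
  dimnames(pmat) <- list(ids, ids)
  pmat
}

#' Probability-of-connectivity numerator
#'
#' `sum_i sum_j a_i a_j p*_ij` over all ordered node pairs (m^4). The
#' landscape-area denominator of the full PC index is deliberately omitted:
#' with a fixed study area it only rescales, and the raw numerator compares
#' scenarios directly. Self-pairs (`i = j`, `p* = 1`) are included by
#' default, following the standard Conefor-style definition; set
#' `include_self = FALSE` for the variant without them.
#'
#' @param pairs matrix from [max_product_paths()].
#' @param areas named numeric vector of node areas (m2) covering all nodes in
#'   `pairs`, or a [waterhole_table()].
#' @param include_self include `a_i^2` self terms (default `TRUE`).
#' @return the PC numerator (m^4).
#' @export
pc_numerator <- function(pairs, areas, include_self = TRUE) {
  if (inherits(areas, "waterhole_table"))
    areas <- stats::setNames(areas$area_m2, areas$id)
  ids <- rownames(pairs)
  if (!all(ids %in% names(areas))) abort_validation("node without an area value")
  a <- areas[ids]
  if (any(!is.finite(a)) || any(a <= 0)) abort_validation("areas must be positive")
  total <- as.numeric(t(a) %*% pairs %*% a)
  if (!include_self) total <- total - sum(a^2)
  total
}

#' Patch-removal node importance (dPC)
#'
#' Recomputes the PC numerator with each node removed in turn:
#' `dPC_k = 100 (PC - PC_{-k}) / PC`. Because removing a node can only
#' remove terms and never improves any surviving path, `dPC >= 0`. Rank 1 is
#' the most important node; ties are broken by larger area, then id.
#'
#' @param network a pruned [resource_network()].
#' @param kernel a [calibrate_kernel()] result.
#' @param mode passed to [max_product_paths()].
#' @param include_self passed to [pc_numerator()].
#' @return a `connectivity_result`: data.frame with `id`, `area_m2`, `dPC`,
#'   `rank`; attributes `pc_numerator`, `d_max` and the pairwise matrix.
#' @export
node_importance <- function(network, kernel, mode = "max_product",
                            include_self = TRUE) {
  if (nrow(network$nodes) < 1) abort_validation("network has no nodes")
  network <- assign_link_probabilities(network, kernel)
  pairs <- max_product_paths(network, mode = mode)
  areas <- stats::setNames(network$nodes$area_m2, network$nodes$id)
  pc <- pc_numerator(pairs, areas, include_self = include_self)
  ids <- network$nodes$id
  dpc <- vapply(ids, function(k) {
    keep <- network$nodes$id != k
    sub_nodes <- network$nodes[keep, , drop = FALSE]
    sub_links <- network$links[network$links$from != k & network$links$to != k, ,
                               drop = FALSE]
    sub <- resource_network(sub_nodes, sub_links, threshold = network$threshold)
    pc_k <- if (nrow(sub_nodes) == 0) 0 else
      pc_numerator(max_product_paths(sub, mode = mode),
                   areas, include_self = include_self)
    100 * (pc - pc_k) / pc
  }, numeric(1))
  dpc <- as.numeric(dpc)
  dpc[dpc < 0 & dpc > -1e-9] <- 0   # clamp float noise; true negatives surface
  res <- data.frame(id = ids, area_m2 = network$nodes$area_m2, dPC = dpc,
                    stringsAsFactors = FALSE)
  res$rank <- importance_rank(res$dPC, res$area_m2, res$id)
  attr(res, "pc_numerator") <- pc
  attr(res, "d_max") <- kernel$d_max
  attr(res, "pairs") <- pairs
  class(res) <- c("connectivity_result", "data.frame")
  res
}

# rank 1 = largest score; ties by larger area then lexical id
importance_rank <- function(score, area, id) {
  ord <- order(-score, -area, id)
  rk <- integer(length(score))
  rk[ord] <- seq_along(score)
  rk
}

#' Aggregate node importance across movement distances
#'
#' Sums per-node dPC over a list of [node_importance()] results computed at
#' different movement thresholds on the same node set, and re-ranks by the
#' aggregate (ties by larger area, then id). This mirrors pooling a node's
#' contribution over the whole range of species movement capacities.
#'
#' @param results list of `connectivity_result` objects on identical node sets.
#' @return data.frame `id`, `area_m2`, one `dPC_<d_max>` column per input,
#'   `total_dPC`, `rank`.
#' @export
aggregate_importance <- function(results) {
  if (!length(results)) abort_validation("no results to aggregate")
  ids <- results[[1]]$id
  for (r in results) {
    if (!identical(sort(r$id), sort(ids)))
      abort_validation("results have mismatched node sets")
  }
  out <- data.frame(id = ids, area_m2 = results[[1]]$area_m2,
                    stringsAsFactors = FALSE)
  total <- numeric(length(ids))
  for (j in seq_along(results)) {
    r <- results[[j]]
    v <- r$dPC[match(ids, r$id)]
    dm <- attr(r, "d_max")
    nm <- if (!is.null(dm)) sprintf("dPC_%g", dm) else sprintf("dPC_%d", j)
    while (nm %in% names(out)) nm <- paste0(nm, "_")
    out[[nm]] <- v
    total <- total + v
  }
  out$total_dPC <- total
  out$rank <- importance_rank(out$total_dPC, out$area_m2, out$id)
  out
}
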