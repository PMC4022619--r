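# Independent oracles and fixture builders. Everything here is deliberately
# written from first principles, not via the package's implementation paths
# (no igraph, no polyclip, no pracma).

# --- polygon oracles -------------------------------------------------------

shoelace_area <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

shoelace_centroid <- function(x, y) {
  n <- length(x); s <- 0; cx <- 0; cy <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- x[i] * y[j] - x[j] * y[i]
    s <- s + cr
    cx <- cx + (x[i] + x[j]) * cr
    cy <- cy + (y[i] + y[j]) * cr
  }
  c(cx, cy) / (3 * s)
}

# classic even-odd ray casting (points assumed off the boundary)
ray_cast_inside <- function(px, py, poly) {
  n <- length(poly$x)
  inside <- logical(length(px))
  for (p in seq_along(px)) {
    cross <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- poly$x[i]; yi <- poly$y[i]; xj <- poly$x[j]; yj <- poly$y[j]
      if ((yi > py[p]) != (yj > py[p]) &&
          px[p] < (xj - xi) * (py[p] - yi) / (yj - yi) + xi) {
        cross <- !cross
      }
      j <- i
    }
    inside[p] <- cross
  }
  inside
}

# random simple (convex-hull star) polygon around a centre
random_polygon <- function(n_vertices = 8, cx = 0, cy = 0, r_range = c(1, 5)) {
  theta <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, r_range[1], r_range[2])
  list(x = cx + r * cos(theta), y = cy + r * sin(theta))
}

# --- graph oracles ---------------------------------------------------------

# union-find connected components; returns integer labels per id
uf_components <- function(ids, from, to) {
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    ri <- find(match(from[e], ids)); rj <- find(match(to[e], ids))
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_along(ids), find, numeric(1))
  match(roots, unique(roots))
}

# exhaustive simple-path enumeration: max product of edge probabilities
# between every pair; adj is an n x n probability matrix (0 = no edge)
brute_max_product <- function(adj) {
  n <- nrow(adj)
  best <- matrix(0, n, n); diag(best) <- 1
  extend <- function(path, prob) {
    tail_node <- path[length(path)]
    src <- path[1]
    if (prob > best[src, tail_node]) best[src, tail_node] <<- prob
    for (v in seq_len(n)) {
      if (adj[tail_node, v] > 0 && !(v %in% path)) {
        extend(c(path, v), prob * adj[tail_node, v])
      }
    }
  }
  for (s in seq_len(n)) extend(s, 1)
  pmax(best, t(best))
}

brute_pc <- function(adj, areas, include_self = TRUE) {
  p <- brute_max_product(adj)
  total <- 0
  n <- length(areas)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j && !include_self) next
    total <- total + areas[i] * areas[j] * p[i, j]
  }
  total
}

# --- fixtures --------------------------------------------------------------

random_table <- function(n, extent = c(10000, 10000), area_range = c(800, 150000)) {
  waterhole_table(
    id = sprintf("n%02d", seq_len(n)),
    x = stats::runif(n, 0, extent[1]),
    y = stats::runif(n, 0, extent[2]),
    area_m2 = stats::runif(n, area_range[1], area_range[2])
  )
}

# random pruned network with kernel probabilities assigned
random_geom_network <- function(n, d_max, extent = c(10000, 10000),
                                tail_prob = 0.05) {
  tab <- random_table(n, extent)
  net <- prune_by_distance(build_complete_network(tab), d_max)
  assign_link_probabilities(net, calibrate_kernel(d_max, tail_prob))
}

# adjacency probability matrix of a network (0 where no link)
network_adjacency <- function(net) {
  ids <- net$nodes$id
  adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in seq_len(nrow(net$links))) {
    i <- match(net$links$from[e], ids); j <- match(net$links$to[e], ids)
    adj[i, j] <- adj[j, i] <- net$links$probability[e]
  }
  adj
}

# Monte-Carlo area of the union of discs (footprint radius + buffer) clipped
# to a rectangular boundary given as list(x, y)
mc_buffer_union_area <- function(tab, radius, boundary, n_pts = 4e5) {
  xr <- range(boundary$x); yr <- range(boundary$y)
  px <- stats::runif(n_pts, xr[1], xr[2])
  py <- stats::runif(n_pts, yr[1], yr[2])
  reach <- sqrt(tab$area_m2 / pi) + radius
  covered <- rep(FALSE, n_pts)
  for (i in seq_len(nrow(tab))) {
    covered <- covered | ((px - tab$x[i])^2 + (py - tab$y[i])^2 <= reach[i]^2)
  }
  mean(covered) * diff(xr) * diff(yr)
}
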