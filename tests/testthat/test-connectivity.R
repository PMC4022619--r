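# Dispersal kernel, max-product path probabilities, PC numerator, dPC.

test_that("kernel calibration pins the tail probability at d_max", {
  k13 <- calibrate_kernel(13000)
  expect_equal(k13$p(13000), 0.05, tolerance = 1e-12)
  expect_equal(k13$p(0), 1)
  expect_equal(k13$k, -log(0.05) / 13000, tolerance = 1e-12)
  expect_equal(k13$p(6500), sqrt(0.05), tolerance = 1e-12)
  for (d in c(2240, 3000, 5000, 16000)) {
    expect_equal(calibrate_kernel(d)$p(d), 0.05, tolerance = 1e-12)
  }
  expect_equal(calibrate_kernel(10000, 0.2)$p(10000), 0.2, tolerance = 1e-12)
  expect_error(calibrate_kernel(-1), class = "aguadas_validation_error")
  expect_error(calibrate_kernel(1000, 0), class = "aguadas_validation_error")
  expect_error(calibrate_kernel(1000, 1), class = "aguadas_validation_error")
})

test_that("link probabilities are exp(-k * length), only on pruned networks", {
  tab <- waterhole_table(c("a", "b", "c"), c(0, 0, 5000), c(0, 5000, 0),
                         c(1000, 1000, 1000))
  kern <- calibrate_kernel(5000)
  net <- assign_link_probabilities(
    prune_by_distance(build_complete_network(tab), 5000), kern)
  expect_equal(net$links$probability[net$links$length == 5000][1], 0.05,
               tolerance = 1e-12)

  set.seed(30)
  rnet <- random_geom_network(20, 4000)
  expect_equal(rnet$links$probability,
               exp(log(0.05) / 4000 * rnet$links$length), tolerance = 1e-12)
  expect_true(all(rnet$links$probability >= 0.05 - 1e-12 &
                    rnet$links$probability <= 1))
  unpruned <- build_complete_network(random_table(5))
  expect_error(assign_link_probabilities(unpruned, calibrate_kernel(1)),
               class = "aguadas_validation_error")
})

test_that("max-product probabilities match exhaustive path enumeration", {
  # two-link chain, no direct link
  tab <- waterhole_table(c("a", "b", "c"), c(0, 1000, 2000), c(0, 0, 0),
                         rep(1000, 3))
  net <- prune_by_distance(build_complete_network(tab), 1000)
  net$links$probability <- c(0.9, 0.9)
  p <- max_product_paths(net)
  expect_equal(p["a", "c"], 0.81, tolerance = 1e-12)
  expect_equal(diag(p), c(a = 1, b = 1, c = 1))

  # disconnected pair
  tab2 <- waterhole_table(c("a", "b"), c(0, 1e6), c(0, 0), c(10, 10))
  p2 <- max_product_paths(
    assign_link_probabilities(prune_by_distance(build_complete_network(tab2), 10),
                              calibrate_kernel(10)))
  expect_equal(p2["a", "b"], 0)

  set.seed(77)
  for (rep in 1:25) {
    net <- random_geom_network(sample(4:8, 1), 4500, extent = c(8000, 8000))
    p <- max_product_paths(net)
    oracle <- brute_max_product(network_adjacency(net))
    expect_equal(unname(p), unname(oracle), tolerance = 1e-12)
  }
})

test_that("with a Euclidean kernel, p* equals exp(-k * shortest path length)", {
  set.seed(13)
  for (rep in 1:10) {
    net <- random_geom_network(12, 3500, extent = c(9000, 9000))
    kern <- calibrate_kernel(3500)
    p <- max_product_paths(net)
    g <- igraph::graph_from_data_frame(net$links, directed = FALSE,
                                       vertices = net$nodes$id)
    sp <- igraph::distances(g, weights = igraph::E(g)$length)
    sp <- sp[rownames(p), colnames(p)]
    expect_equal(unname(p), unname(exp(-kern$k * sp)), tolerance = 1e-10)
  }
})

test_that("PC numerator follows the ordered-pair definition with self terms", {
  one <- matrix(1, 1, 1, dimnames = list("a", "a"))
  expect_equal(pc_numerator(one, c(a = 2)), 4)

  two <- diag(2); dimnames(two) <- list(c("a", "b"), c("a", "b"))
  expect_equal(pc_numerator(two, c(a = 2, b = 3)), 13)

  linked <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(pc_numerator(linked, c(a = 2, b = 3)), 19)
  expect_equal(pc_numerator(linked, c(a = 2, b = 3), include_self = FALSE), 6)
  expect_error(pc_numerator(linked, c(a = 2)), class = "aguadas_validation_error")
})

test_that("component-indicator mode gives p* = 1 within components", {
  set.seed(41)
  net <- random_geom_network(15, 2500, extent = c(12000, 12000))
  p <- max_product_paths(net, mode = "component")
  pm <- max_product_paths(net)
  expect_true(all(p %in% c(0, 1)))
  expect_equal(p > 0, pm > 0)
})

test_that("dPC matches naive leave-one-out recomputation and is well-behaved", {
  # symmetry: two identical nodes share a link
  tab <- waterhole_table(c("a", "b"), c(0, 1000), c(0, 0), c(5000, 5000))
  res <- node_importance(prune_by_distance(build_complete_network(tab), 2000),
                         calibrate_kernel(2000))
  expect_equal(res$dPC[1], res$dPC[2])

  # isolated node: dPC = 100 a_k^2 / PC
  tab2 <- waterhole_table(c("a", "b", "c"), c(0, 1000, 50000), c(0, 0, 0),
                          c(2000, 3000, 4000))
  net2 <- assign_link_probabilities(
    prune_by_distance(build_complete_network(tab2), 2000), calibrate_kernel(2000))
  pc <- pc_numerator(max_product_paths(net2), stats::setNames(tab2$area_m2, tab2$id))
  res2 <- node_importance(prune_by_distance(build_complete_network(tab2), 2000),
                          calibrate_kernel(2000))
  expect_equal(res2$dPC[res2$id == "c"], 100 * 4000^2 / pc, tolerance = 1e-12)

  # single node: dPC = 100
  single <- node_importance(build_complete_network(tab2[1, ]), calibrate_kernel(1000))
  expect_equal(single$dPC, 100)

  # random instances vs a fully independent leave-one-out oracle
  set.seed(55)
  for (rep in 1:5) {
    net <- random_geom_network(10, 4000, extent = c(9000, 9000))
    res <- node_importance(net, calibrate_kernel(4000))
    adj <- network_adjacency(net)
    areas <- net$nodes$area_m2
    pc_full <- brute_pc(adj, areas)
    expect_equal(attr(res, "pc_numerator"), pc_full, tolerance = 1e-9)
    for (k in seq_len(10)) {
      pc_k <- brute_pc(adj[-k, -k, drop = FALSE], areas[-k])
      expect_equal(res$dPC[res$id == net$nodes$id[k]],
                   100 * (pc_full - pc_k) / pc_full, tolerance = 1e-9)
    }
    expect_true(all(res$dPC >= 0 & res$dPC <= 100))
    expect_setequal(res$rank, 1:10)
  }
})

test_that("dPC is not monotone in waterhole area alone", {
  # a well-placed small waterhole can outrank a larger, isolated one
  tab <- waterhole_table(
    id = c("bigA", "bigC", "lonely"),
    x = c(0, 1000, 80000), y = c(0, 0, 80000),
    area_m2 = c(50000, 50000, 60000)
  )
  res <- node_importance(prune_by_distance(build_complete_network(tab), 2500),
                         calibrate_kernel(2500))
  dpc <- stats::setNames(res$dPC, res$id)
  expect_gt(dpc[["bigA"]], dpc[["lonely"]])
  expect_gt(tab$area_m2[3], tab$area_m2[1])
})

test_that("importance aggregates across distances by per-node summation", {
  set.seed(91)
  tab <- random_table(12, extent = c(10000, 10000))
  complete <- build_complete_network(tab)
  distances <- c(3000, 5000, 8000)
  results <- lapply(distances, function(d)
    node_importance(prune_by_distance(complete, d), calibrate_kernel(d)))
  agg <- aggregate_importance(results)
  manual <- Reduce(`+`, lapply(results, function(r) r$dPC[match(agg$id, r$id)]))
  expect_equal(agg$total_dPC, manual, tolerance = 1e-12)
  expect_setequal(agg$rank, 1:12)

  # identical results at every distance: aggregate = n x single, same ranking
  same <- aggregate_importance(results[c(1, 1, 1, 1, 1)])
  expect_equal(same$total_dPC, 5 * results[[1]]$dPC[match(same$id, results[[1]]$id)])
  expect_equal(same$rank, aggregate_importance(results[1])$rank)

  # one distance only: identity
  one <- aggregate_importance(results[2])
  expect_equal(one$total_dPC, results[[2]]$dPC[match(one$id, results[[2]]$id)])

  # mismatched node sets: validation error
  res_small <- node_importance(prune_by_distance(build_complete_network(tab[1:10, ]), 3000),
                               calibrate_kernel(3000))
  expect_error(aggregate_importance(list(results[[1]], res_small)),
               class = "aguadas_validation_error")
})
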