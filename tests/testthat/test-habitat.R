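# Buffer-union suitable habitat: footprints, union area, patch counts.

big_boundary <- function(half = 50000) {
  study_area(list(x = c(-half, half, half, -half),
                  y = c(-half, -half, half, half)))
}

test_that("synthetic footprints are near-exact discs; stored ones pass through", {
  a <- pi * 100^2
  tab <- waterhole_table("w", 0, 0, a)
  fp <- waterhole_footprint(tab, 1)
  expect_equal(max(sqrt(fp$x^2 + fp$y^2)), 100, tolerance = 1e-9)
  expect_equal(polygon_area(fp), a, tolerance = 0.005)

  sq <- list(x = c(-50, 50, 50, -50), y = c(-50, -50, 50, 50))
  tab2 <- waterhole_table("w", 0, 0, 10000, footprint = list(sq))
  expect_identical(waterhole_footprint(tab2, 1), sq)

  tiny <- waterhole_table("w", 0, 0, 1e-6)
  expect_equal(polygon_area(waterhole_footprint(tiny, 1)), 1e-6, tolerance = 0.005)
})

test_that("a single buffered waterhole recovers the closed-form disc area", {
  tab <- waterhole_table("w", 0, 0, pi * 100^2)
  hs <- buffered_habitat(tab, 1000, big_boundary())
  expect_equal(hs$total_area, pi * 1100^2, tolerance = 0.005)
  expect_equal(hs$n_patches, 1)
  expect_equal(hs$percent_of_study_area, 100 * hs$total_area / (100000^2))
})

test_that("patch counts reflect buffer overlap", {
  # 10 km apart, reach 1.1 km each: disjoint
  two_far <- waterhole_table(c("a", "b"), c(0, 10000), c(0, 0),
                             rep(pi * 100^2, 2))
  expect_equal(buffered_habitat(two_far, 1000, big_boundary())$n_patches, 2)
  # 1.5 km apart, combined reach 2.2 km: overlap
  two_near <- waterhole_table(c("a", "b"), c(0, 1500), c(0, 0),
                              rep(pi * 100^2, 2))
  expect_equal(buffered_habitat(two_near, 1000, big_boundary())$n_patches, 1)
  # empty table: zero-area summary
  empty <- buffered_habitat(two_far[0, ], 1000, big_boundary())
  expect_equal(empty$total_area, 0)
  expect_equal(empty$n_patches, 0)
})

test_that("union area matches a Monte-Carlo point-sampling oracle within 1%", {
  set.seed(60)
  boundary <- study_area(list(x = c(0, 12000, 12000, 0), y = c(0, 0, 12000, 12000)))
  for (rep in 1:10) {
    tab <- random_table(10, extent = c(12000, 12000), area_range = c(5000, 150000))
    hs <- buffered_habitat(tab, 1000, boundary)
    mc <- mc_buffer_union_area(tab, 1000, boundary$boundary, n_pts = 4e5)
    expect_equal(hs$total_area, mc, tolerance = 0.01)
  }
})

test_that("patch count equals a disc-overlap graph oracle", {
  set.seed(61)
  boundary <- big_boundary()
  rep_done <- 0
  while (rep_done < 8) {
    tab <- random_table(12, extent = c(15000, 15000), area_range = c(2000, 100000))
    reach <- sqrt(tab$area_m2 / pi) + 1000
    d <- as.matrix(stats::dist(cbind(tab$x, tab$y)))
    slack <- abs(d - outer(reach, reach, "+"))
    if (min(slack[upper.tri(slack)]) < 10) next  # skip near-tangent layouts
    from <- character(0); to <- character(0)
    for (i in 1:11) for (j in (i + 1):12) {
      if (d[i, j] < reach[i] + reach[j]) {
        from <- c(from, tab$id[i]); to <- c(to, tab$id[j])
      }
    }
    n_groups <- length(unique(uf_components(tab$id, from, to)))
    hs <- buffered_habitat(tab, 1000, boundary)
    expect_equal(hs$n_patches, n_groups)
    rep_done <- rep_done + 1
  }
})

test_that("union area is order-invariant, subadditive and monotone under deletion", {
  set.seed(62)
  boundary <- big_boundary()
  tab <- random_table(15, extent = c(8000, 8000), area_range = c(2000, 120000))
  hs <- buffered_habitat(tab, 1000, boundary)
  shuffled <- buffered_habitat(tab[sample(15), ], 1000, boundary)
  expect_equal(hs$total_area, shuffled$total_area, tolerance = 1e-6)

  individual <- sum(vapply(seq_len(15), function(i)
    buffered_habitat(tab[i, ], 1000, boundary)$total_area, numeric(1)))
  expect_lte(hs$total_area, individual + 1e-6)

  drop_one <- buffered_habitat(tab[-3, ], 1000, boundary)
  expect_lte(drop_one$total_area, hs$total_area + 1e-6)
})

test_that("habitat sweep is monotone along scenarios and clipped to the boundary", {
  set.seed(63)
  tab <- random_table(25, extent = c(10000, 10000), area_range = c(800, 150000))
  area <- study_area(list(x = c(0, 10000, 10000, 0), y = c(0, 0, 10000, 10000)))
  hab <- habitat_sweep(tab, default_scenarios(), radii = c(1000, 2000), area)
  expect_equal(nrow(hab), 22)
  for (r in c(1000, 2000)) {
    h <- hab[hab$buffer_radius == r, ]
    expect_true(all(diff(h$percent_of_study_area) <= 1e-9))
    expect_true(all(h$percent_of_study_area >= 0 & h$percent_of_study_area <= 100))
    expect_true(all(h$n_patches <= pmax(h$n_waterholes, 1)))
  }
  # scenario removing nothing: identical to base
  none <- drought_scenario("none", 0)
  base_direct <- buffered_habitat(apply_scenario(tab, none), 1000, area)
  expect_equal(hab$total_area[hab$scenario == "A" & hab$buffer_radius == 1000],
               base_direct$total_area)
})

test_that("habitat unions export as valid GeoJSON MultiPolygons", {
  tab <- waterhole_table(c("a", "b"), c(0, 1500), c(0, 0), rep(pi * 100^2, 2))
  hs <- buffered_habitat(tab, 1000, big_boundary())
  f <- withr::local_tempfile(fileext = ".geojson")
  write_habitat_geojson(hs, f)
  gj <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(gj$features[[1]]$geometry$type, "MultiPolygon")
  expect_equal(length(gj$features[[1]]$geometry$coordinates), hs$n_patches)
})
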