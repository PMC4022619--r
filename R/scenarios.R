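# Area-ordered drought deletion scenarios and the scenario x distance sweep.

#' Default drought scenarios A-K
#'
#' Drought is emulated by deleting waterholes in increasing order of surface
#' area: field observations show the smallest waterholes dry first. The base
#' scenario A keeps every waterhole strictly larger than `base_min_area`
#' (700 m2); each drought scenario B-K additionally removes waterholes with
#' area less than or equal to its `removal_threshold`.
#'
#' @param base_min_area minimum area (m2) for inclusion in the base network;
#'   strictly-greater-than filter (default 700).
#' @return a `drought_scenarios` data.frame with columns `label`,
#'   `removal_threshold` (m2), `base_min_area`.
#' @export
default_scenarios <- function(base_min_area = 700) {
  thresholds <- c(0, 1000, 2500, 5625, 10000, 15625, 22500, 30600, 40000,
                  50600, 62500)
  out <- data.frame(label = LETTERS[1:11], removal_threshold = thresholds,
                    base_min_area = base_min_area, stringsAsFactors = FALSE)
  class(out) <- c("drought_scenarios", "data.frame")
  out
}

#' Construct a drought scenario
#'
#' @param label scenario label.
#' @param removal_threshold area T (m2): waterholes with area `<= T` are
#'   removed (inclusive boundary).
#' @param base_min_area base-network minimum area (m2, strict `>`).
#' @return one-row `drought_scenarios` data.frame.
#' @export
drought_scenario <- function(label, removal_threshold, base_min_area = 700) {
  if (!is.finite(removal_threshold) || removal_threshold < 0)
    abort_validation("removal_threshold must be >= 0")
  out <- data.frame(label = as.character(label),
                    removal_threshold = removal_threshold,
                    base_min_area = base_min_area, stringsAsFactors = FALSE)
  class(out) <- c("drought_scenarios", "data.frame")
  out
}

#' Apply a drought scenario to a waterhole table
#'
#' Keeps waterholes with `area > base_min_area` (base filter, strict) and
#' `area > removal_threshold` (scenario filter: area at exactly the
#' threshold is removed). Row order is preserved; an empty result is allowed
#' (severe drought).
#'
#' @param tab a [waterhole_table()].
#' @param scenario one row of a `drought_scenarios` table (or a one-row
#'   [drought_scenario()]).
#' @return the filtered [waterhole_table()].
#' @export
apply_scenario <- function(tab, scenario) {
  keep <- tab$area_m2 > scenario$base_min_area[1] &
    tab$area_m2 > scenario$removal_threshold[1]
  tab[keep, , drop = FALSE]
}

#' Run the scenario x distance sweep
#'
#' For every (scenario, distance) combination: filter the table by the
#' scenario, build the complete centroid graph, prune at the distance,
#' and record structural metrics plus the PC numerator under the dispersal
#' kernel calibrated to that distance. Deterministic for a fixed input.
#'
#' @param tab a [waterhole_table()].
#' @param scenarios a `drought_scenarios` table (default [default_scenarios()]).
#' @param distances movement-distance thresholds (m).
#' @param tail_prob dispersal-kernel tail probability at `d_max`
#'   (default 0.05).
#' @param include_self include self-pairs in the PC numerator.
#' @param mode pairwise-probability mode, see [max_product_paths()].
#' @return data.frame with one row per (scenario, distance): `scenario`,
#'   `distance`, `n_nodes`, `total_water_area`, `n_links`, `link_density`,
#'   `n_clusters`, `pc_numerator`.
#' @export
run_sweep <- function(tab, scenarios = default_scenarios(),
                      distances = c(3000, 5000, 10000, 13000, 16000),
                      tail_prob = 0.05, include_self = TRUE,
                      mode = "max_product") {
  if (!nrow(scenarios) || !length(distances))
    abort_validation("need at least one scenario and one distance")
  if (any(distances <= 0)) abort_validation("distances must be > 0")
  rows <- vector("list", nrow(scenarios) * length(distances))
  r <- 0L
  for (s in seq_len(nrow(scenarios))) {
    sub <- apply_scenario(tab, scenarios[s, ])
    complete <- if (nrow(sub)) build_complete_network(sub) else NULL
    for (d in distances) {
      r <- r + 1L
      if (is.null(complete)) {
        rows[[r]] <- data.frame(scenario = scenarios$label[s], distance = d,
                                n_nodes = 0L, total_water_area = 0,
                                n_links = 0L, link_density = 0,
                                n_clusters = 0L, pc_numerator = 0,
                                stringsAsFactors = FALSE)
        next
      }
      net <- prune_by_distance(complete, d)
      met <- compute_metrics(net)
      kern <- calibrate_kernel(d, tail_prob)
      net <- assign_link_probabilities(net, kern)
      pairs <- max_product_paths(net, mode = mode)
      pc <- pc_numerator(pairs, stats::setNames(sub$area_m2, sub$id),
                         include_self = include_self)
      rows[[r]] <- data.frame(scenario = scenarios$label[s], distance = d,
                              n_nodes = met$n_nodes,
                              total_water_area = met$total_water_area,
                              n_links = met$n_links,
                              link_density = met$link_density,
                              n_clusters = met$n_clusters,
                              pc_numerator = pc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Species movement-distance presets
#'
#' Named movement-distance ranges (m) reported for the three focal species,
#' resolved against a distance list: a preset keeps the distances falling
#' inside the species' reported minimum-maximum travel range.
#'
#' @param species one of `"tapir"` (3-13 km), `"peccary"` (3-16 km),
#'   `"jaguar"` (2240-10000 m).
#' @param distances candidate distance list (m); defaults to the standard
#'   sweep set.
#' @return numeric vector of distances (m) within the species' range.
#' @export
species_distances <- function(species = c("tapir", "peccary", "jaguar"),
                              distances = c(3000, 5000, 10000, 13000, 16000)) {
  species <- match.arg(species)
  rng <- switch(species,
                tapir = c(3000, 13000),
                peccary = c(3000, 16000),
                jaguar = c(2240, 10000))
  distances[distances >= rng[1] & distances <= rng[2]]
}
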