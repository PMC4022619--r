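# Waterhole layers: construction, validation, reserve tagging, CSV/GeoJSON io.

#' Construct a waterhole table
#'
#' A waterhole table is a `data.frame` (class `waterhole_table`) with one row
#' per waterhole: `id` (unique character), `x`, `y` (projected metres),
#' `area_m2` (> 0), an optional `footprint` list-column of polygon rings, and
#' an optional logical `in_reserve`. Centroid plus surface area is the
#' canonical representation; footprints, when stored, must agree with it
#' (area within 0.5%, centroid within 1 m).
#'
#' @param id character vector of unique identifiers.
#' @param x,y centroid coordinates in a projected metric CRS.
#' @param area_m2 surface areas in square metres, all > 0.
#' @param footprint optional list of polygon rings (each `list(x, y)`), or
#'   `NULL` entries for waterholes without a stored footprint.
#' @param in_reserve optional logical vector.
#' @param source provenance note (file path or generator description).
#' @return a `waterhole_table`.
#' @export
waterhole_table <- function(id, x, y, area_m2, footprint = NULL,
                            in_reserve = NULL, source = NA_character_) {
  id <- as.character(id)
  tab <- data.frame(id = id, x = as.numeric(x), y = as.numeric(y),
                    area_m2 = as.numeric(area_m2), stringsAsFactors = FALSE)
  if (!is.null(footprint)) {
    stopifnot(length(footprint) == nrow(tab))
    tab$footprint <- I(footprint)
  }
  if (!is.null(in_reserve)) tab$in_reserve <- as.logical(in_reserve)
  attr(tab, "source") <- source
  class(tab) <- c("waterhole_table", "data.frame")
  validate_waterhole_table(tab)
  tab
}

#' Validate a waterhole table
#'
#' Checks id uniqueness, coordinate finiteness, positive areas, and
#' footprint consistency (footprint area within 0.5% of `area_m2`, centroid
#' within 1 m of `(x, y)`).
#'
#' @param tab a `waterhole_table`.
#' @return the table, invisibly, if valid; otherwise a validation error.
#' @export
validate_waterhole_table <- function(tab) {
  if (nrow(tab) == 0) return(invisible(tab))
  if (anyDuplicated(tab$id)) abort_validation("duplicate waterhole ids")
  if (!all(is.finite(tab$x)) || !all(is.finite(tab$y)))
    abort_validation("non-finite coordinates")
  if (!all(is.finite(tab$area_m2)) || any(tab$area_m2 <= 0))
    abort_validation("waterhole areas must be positive")
  if (!is.null(tab$footprint)) {
    for (i in seq_len(nrow(tab))) {
      fp <- tab$footprint[[i]]
      if (is.null(fp)) next
      a <- polygon_area(fp)
      if (abs(a - tab$area_m2[i]) > 0.005 * tab$area_m2[i])
        abort_validation(sprintf("footprint area of '%s' disagrees with area_m2", tab$id[i]))
      ctr <- polygon_centroid(fp)
      if (sqrt((ctr[1] - tab$x[i])^2 + (ctr[2] - tab$y[i])^2) > 1)
        abort_validation(sprintf("footprint centroid of '%s' disagrees with (x, y)", tab$id[i]))
    }
  }
  invisible(tab)
}

#' @export
print.waterhole_table <- function(x, ...) {
  cat(sprintf("Waterhole table: %d waterholes, total water area %.3f km2\n",
              nrow(x), sum(x$area_m2) / 1e6))
  if (!is.null(x$in_reserve))
    cat(sprintf("  in reserve: %d / %d\n", sum(x$in_reserve), nrow(x)))
  NextMethod()
}

#' Construct a study area
#'
#' @param boundary polygon ring (`list(x, y)`, projected metres) of the study
#'   extent.
#' @param reserve optional polygon ring of the protected-area boundary; must
#'   lie within `boundary` (intersection area equal to the reserve area
#'   within 0.1%).
#' @return a `study_area` object.
#' @export
study_area <- function(boundary, reserve = NULL) {
  if (!is_ring(boundary)) abort_validation("boundary must be a polygon ring")
  if (polygon_area(boundary) <= 0) abort_validation("boundary area must be > 0")
  if (!is.null(reserve)) {
    if (!is_ring(reserve)) abort_validation("reserve must be a polygon ring")
    inter <- polyclip::polyclip(reserve, boundary, op = "intersection")
    a_int <- sum(vapply(inter, polygon_area, numeric(1)))
    a_res <- polygon_area(reserve)
    if (abs(a_int - a_res) > 0.001 * a_res)
      abort_validation("reserve polygon does not lie within the study boundary")
  }
  structure(list(boundary = boundary, reserve = reserve), class = "study_area")
}

#' @export
print.study_area <- function(x, ...) {
  a <- polygon_area(x$boundary)
  cat(sprintf("Study area: %.1f km2", a / 1e6))
  if (!is.null(x$reserve))
    cat(sprintf("; reserve %.1f km2 (%.1f%%)",
                polygon_area(x$reserve) / 1e6, 100 * polygon_area(x$reserve) / a))
  cat("\n")
  invisible(x)
}

#' Read a waterhole layer
#'
#' Reads a waterhole layer from CSV (columns `id,x,y,area_m2`) or GeoJSON
#' (RFC 7946). GeoJSON `Point` features must carry an `area_m2` property;
#' `Polygon` features get centroid and area computed from the exterior ring
#' and the ring stored as the footprint.
#'
#' @param path input file.
#' @param format `"csv"`, `"geojson"`, or `"auto"` (by file extension).
#' @return a [waterhole_table()].
#' @export
read_waterholes <- function(path, format = c("auto", "csv", "geojson")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) "geojson" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "x", "y", "area_m2")
    miss <- setdiff(need, names(df))
    if (length(miss))
      abort_format(sprintf("CSV missing column(s): %s", paste(miss, collapse = ", ")))
    inres <- if ("in_reserve" %in% names(df)) as.logical(df$in_reserve) else NULL
    return(waterhole_table(df$id, df$x, df$y, df$area_m2,
                           in_reserve = inres, source = path))
  }
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  n <- length(feats)
  if (n == 0) abort_format("GeoJSON contains no features")
  id <- character(n); x <- numeric(n); y <- numeric(n); area <- numeric(n)
  fps <- vector("list", n)
  for (i in seq_len(n)) {
    f <- feats[[i]]
    props <- f$properties
    id[i] <- as.character(
      if (!is.null(props$id)) props$id else if (!is.null(f$id)) f$id else sprintf("wh%03d", i)
    )
    geom <- f$geometry
    if (identical(geom$type, "Point")) {
      if (is.null(props$area_m2))
        abort_format(sprintf("Point feature '%s' lacks area_m2 property", id[i]))
      x[i] <- geom$coordinates[[1]]; y[i] <- geom$coordinates[[2]]
      area[i] <- as.numeric(props$area_m2)
    } else if (identical(geom$type, "Polygon")) {
      ring <- geom$coordinates[[1]]
      px <- vapply(ring, function(v) as.numeric(v[[1]]), numeric(1))
      py <- vapply(ring, function(v) as.numeric(v[[2]]), numeric(1))
      # GeoJSON rings are closed; store open
      if (px[1] == px[length(px)] && py[1] == py[length(py)]) {
        px <- px[-length(px)]; py <- py[-length(py)]
      }
      fp <- list(x = px, y = py)
      ctr <- polygon_centroid(fp)
      x[i] <- ctr[1]; y[i] <- ctr[2]
      area[i] <- polygon_area(fp)
      fps[[i]] <- fp
    } else {
      abort_format(sprintf("unsupported geometry type '%s'", geom$type))
    }
  }
  footprint <- if (any(!vapply(fps, is.null, logical(1)))) fps else NULL
  waterhole_table(id, x, y, area, footprint = footprint, source = path)
}

#' Read a study area from GeoJSON polygon files
#'
#' @param boundary_path GeoJSON file whose first Polygon feature is the study
#'   boundary.
#' @param reserve_path optional GeoJSON file with the reserve polygon.
#' @return a [study_area()].
#' @export
read_study_area <- function(boundary_path, reserve_path = NULL) {
  study_area(read_polygon_geojson(boundary_path),
             if (!is.null(reserve_path)) read_polygon_geojson(reserve_path))
}

read_polygon_geojson <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    if (identical(geom$type, "Polygon")) {
      ring <- geom$coordinates[[1]]
      px <- vapply(ring, function(v) as.numeric(v[[1]]), numeric(1))
      py <- vapply(ring, function(v) as.numeric(v[[2]]), numeric(1))
      if (px[1] == px[length(px)] && py[1] == py[length(py)]) {
        px <- px[-length(px)]; py <- py[-length(py)]
      }
      return(list(x = px, y = py))
    }
  }
  abort_format(sprintf("no Polygon feature in %s", path))
}

#' Tag reserve membership
#'
#' Sets `in_reserve` for each waterhole by point-in-polygon of its centroid
#' against the reserve polygon. Centroids exactly on the reserve boundary
#' count as inside.
#'
#' @param tab a [waterhole_table()].
#' @param area a [study_area()] with a reserve polygon.
#' @return the table with `in_reserve` filled in.
#' @export
tag_reserve_membership <- function(tab, area) {
  if (is.null(area$reserve)) abort_config("study area has no reserve polygon")
  tab$in_reserve <- point_in_polygon(tab$x, tab$y, area$reserve)
  tab
}

#' Write a tabular result as CSV
#'
#' Any list-columns (footprints) are dropped. An empty table writes a
#' header-only file with a warning.
#'
#' @param records a data.frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  keep <- !vapply(records, is.list, logical(1))
  out <- as.data.frame(records)[, keep, drop = FALSE]
  if (nrow(out) == 0) warning(sprintf("writing empty table to %s", path))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

close_ring <- function(p) {
  lapply(c(seq_along(p$x), 1L), function(i) c(p$x[i], p$y[i]))
}

write_feature_collection <- function(features, path) {
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Export a resource network as GeoJSON
#'
#' Nodes become `Point` features (properties `id`, `area_m2`, and
#' `in_reserve` when present); links become `LineString` features with
#' `length_m` and, when assigned, `probability`.
#'
#' @param network a [resource_network()].
#' @param path output path.
#' @export
write_network_geojson <- function(network, path) {
  nodes <- network$nodes
  feats <- vector("list", nrow(nodes) + nrow(network$links))
  for (i in seq_len(nrow(nodes))) {
    props <- list(id = nodes$id[i], area_m2 = nodes$area_m2[i])
    if (!is.null(nodes$in_reserve)) props$in_reserve <- nodes$in_reserve[i]
    feats[[i]] <- geojson_feature(
      list(type = "Point", coordinates = c(nodes$x[i], nodes$y[i])), props
    )
  }
  for (j in seq_len(nrow(network$links))) {
    l <- network$links[j, ]
    i1 <- match(l$from, nodes$id); i2 <- match(l$to, nodes$id)
    props <- list(from = l$from, to = l$to, length_m = l$length)
    if (!is.na(l$probability)) props$probability <- l$probability
    feats[[nrow(nodes) + j]] <- geojson_feature(
      list(type = "LineString",
           coordinates = list(c(nodes$x[i1], nodes$y[i1]),
                              c(nodes$x[i2], nodes$y[i2]))),
      props
    )
  }
  write_feature_collection(feats, path)
}

#' Write a waterhole table as GeoJSON points
#'
#' @param tab a [waterhole_table()].
#' @param path output path.
#' @export
write_waterholes_geojson <- function(tab, path) {
  feats <- lapply(seq_len(nrow(tab)), function(i) {
    props <- list(id = tab$id[i], area_m2 = tab$area_m2[i])
    if (!is.null(tab$in_reserve)) props$in_reserve <- tab$in_reserve[i]
    geojson_feature(list(type = "Point", coordinates = c(tab$x[i], tab$y[i])), props)
  })
  write_feature_collection(feats, path)
}

#' Write a polygon as a single-feature GeoJSON file
#'
#' @param poly polygon ring (`list(x, y)`).
#' @param path output path.
#' @param properties named list of feature properties.
#' @export
write_polygon_geojson <- function(poly, path, properties = list()) {
  feats <- list(geojson_feature(
    list(type = "Polygon", coordinates = list(close_ring(poly))),
    properties
  ))
  write_feature_collection(feats, path)
}
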