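# GeoJSON and CSV interchange. Coordinates are planar metres; GeoJSON
# features carry "crs": "local-cartesian-metres" in their properties to make
# that explicit.

poly_to_geojson_coords <- function(poly) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  list(apply(ring, 1, function(r) c(r[1], r[2]), simplify = FALSE))
}

feature <- function(geometry_type, coords, properties) {
  list(type = "Feature",
       geometry = list(type = geometry_type, coordinates = coords),
       properties = c(properties, list(crs = "local-cartesian-metres")))
}

#' Write domain geometry as GeoJSON
#'
#' Land polygons, the spawning and strait regions, the gates and the
#' coastal segments, each as a Feature with `label` / `coast` properties.
#'
#' @param domain A `strait_domain`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_domain_geojson <- function(domain, path) {
  feats <- list()
  for (nm in names(domain$land)) {
    feats[[length(feats) + 1]] <- feature(
      "Polygon", poly_to_geojson_coords(domain$land[[nm]]),
      list(label = nm, kind = "land"))
  }
  feats[[length(feats) + 1]] <- feature(
    "Polygon", poly_to_geojson_coords(domain$spawning_region),
    list(label = "spawning_region", kind = "region"))
  feats[[length(feats) + 1]] <- feature(
    "Polygon", poly_to_geojson_coords(domain$strait_region),
    list(label = "strait_region", kind = "region"))
  for (nm in names(domain$gates)) {
    g <- domain$gates[[nm]]
    coords <- list(c(g$x[1], g$y), c(g$x[2], g$y))
    feats[[length(feats) + 1]] <- feature(
      "LineString", coords, list(label = paste0(nm, "_gate"), kind = "gate"))
  }
  for (seg in domain$segments) {
    coords <- apply(seg$polyline, 1, function(r) c(r[1], r[2]),
                    simplify = FALSE)
    feats[[length(feats) + 1]] <- feature(
      "LineString", coords,
      list(label = seg$id, coast = seg$coast, kind = "coastal_segment"))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read region polygons from a GeoJSON FeatureCollection
#'
#' @param path GeoJSON file path.
#' @return Named list of two-column polygon matrices, one per Polygon
#'   feature, named by the `label` property.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  out <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon")) next
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    lab <- f$properties$label
    if (is.null(lab)) lab <- paste0("polygon_", length(out) + 1)
    out[[lab]] <- m
  }
  out
}

#' Write a source grid (NSI map) as GeoJSON
#'
#' @param grid A `source_grid` from [compute_nsi()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_source_grid_geojson <- function(grid, path) {
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    poly <- rbind(c(g$x_lo, g$y_lo), c(g$x_hi, g$y_lo),
                  c(g$x_hi, g$y_hi), c(g$x_lo, g$y_hi))
    feature("Polygon", poly_to_geojson_coords(poly),
            list(cell = g$cell, released = g$released, entered = g$entered,
                 nsi = g$nsi,
                 travel_time = if ("travel_time" %in% names(grid)) g$travel_time else NULL))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write stranding events as CSV
#'
#' One row per stranded particle: particle id, stranding time, segment id,
#' coast and contact position.
#'
#' @param ts A `trajectory_set`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_stranding_csv <- function(ts, path) {
  p <- ts$particles
  ev <- p[p$status == "stranded",
          c("id", "status_time", "strand_segment", "strand_coast",
            "x_final", "y_final")]
  names(ev) <- c("particle_id", "time", "segment_id", "coast", "x", "y")
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' Read a current-meter record CSV
#'
#' Expected columns `time`, `u`, `v` (m/s); derives the 2-D speed modulus
#' and the signed along-channel component (positive = northward/flood).
#'
#' @param path CSV file path.
#' @return Data frame with time, u, v, speed, along_component.
#' @export
read_current_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "u", "v") %in% names(raw)))
  raw$speed <- sqrt(raw$u^2 + raw$v^2)
  raw$along_component <- raw$v
  raw
}

#' Read a density-anomaly profile CSV
#'
#' Expected columns `depth` (m) and `sigma_t` (kg/m^3).
#'
#' @param path CSV file path.
#' @return Data frame with depth and sigma_t, ordered by depth.
#' @export
read_profile_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("depth", "sigma_t") %in% names(raw)))
  raw[order(raw$depth), ]
}

#' Write trajectory positions and terminal events as CSV
#'
#' @param ts A `trajectory_set`.
#' @param positions_path,events_path Output file paths (either may be
#'   `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_trajectories_csv <- function(ts, positions_path = NULL,
                                   events_path = NULL) {
  if (!is.null(positions_path)) {
    utils::write.csv(ts$positions, positions_path, row.names = FALSE)
  }
  if (!is.null(events_path)) {
    utils::write.csv(ts$particles, events_path, row.names = FALSE)
  }
  invisible(c(positions_path, events_path))
}
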