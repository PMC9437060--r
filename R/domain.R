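#' Build the idealized strait-and-basin domain geometry
#'
#' Constructs the planar geometry the synthetic experiments run in: two
#' mainland blocks ("sicily_side" west, "calabria_side" east) separated by a
#' north--south channel, a northern basin holding the island archipelago, a
#' spawning region around the islands, a strait region bounded by two
#' cross-channel gates, the outer open boundary, and the two mainland
#' coastlines pre-segmented into 5-km stretches (ids `Sic1..`, `Cal1..`;
#' Sicily numbered clockwise from the southern channel end, Calabria
#' counter-clockwise).
#'
#' @param config A [flow_config()].
#' @param segment_length Coastal segment length in metres (default 5000).
#' @return An object of class `strait_domain`: a list with land polygons,
#'   named regions, gates, coastlines, coastal segments, grid axes and the
#'   land mask.
#' @export
make_idealized_domain <- function(config = flow_config(), segment_length = 5000) {
  stopifnot(inherits(config, "flow_config"))
  xmax <- config$domain_size[1]; ymax <- config$domain_size[2]
  cw <- config$channel_x[1]; ce <- config$channel_x[2]
  my <- config$mouth_y
  if (ce - cw <= 2 * config$grid_spacing) {
    stop("degenerate geometry: channel width must exceed 2 grid cells", call. = FALSE)
  }

  land <- list(
    sicily_side = rbind(c(0, 0), c(cw, 0), c(cw, my), c(0, my)),
    calabria_side = rbind(c(ce, 0), c(xmax, 0), c(xmax, my), c(ce, my))
  )
  for (nm in names(config$islands)) {
    isl <- config$islands[[nm]]
    land[[paste0("island:", nm)]] <- circle_polygon(isl$centre, isl$radius)
  }

  sb <- config$spawning_box
  spawning <- rbind(c(sb[1], sb[3]), c(sb[2], sb[3]), c(sb[2], sb[4]), c(sb[1], sb[4]))
  gy <- config$gate_y
  strait <- rbind(c(cw, gy[["ionian"]]), c(ce, gy[["ionian"]]),
                  c(ce, gy[["tyrrhenian"]]), c(cw, gy[["tyrrhenian"]]))
  gates <- list(
    tyrrhenian = list(y = gy[["tyrrhenian"]], x = c(cw, ce), outward = +1),
    ionian = list(y = gy[["ionian"]], x = c(cw, ce), outward = -1)
  )

  # Water-facing coastlines, ordered per the segment-numbering convention.
  coasts <- list(
    sicily = rbind(c(cw, 0), c(cw, my), c(0, my)),
    calabria = rbind(c(ce, 0), c(ce, my), c(xmax, my))
  )
  segments <- c(
    segment_coastline(coasts$sicily, segment_length, id_prefix = "Sic", coast = "sicily"),
    segment_coastline(coasts$calabria, segment_length, id_prefix = "Cal", coast = "calabria")
  )

  dx <- config$grid_spacing
  x_axis <- seq(dx / 2, xmax - dx / 2, by = dx)
  y_axis <- seq(dx / 2, ymax - dx / 2, by = dx)
  land_mask <- matrix(FALSE, nrow = length(y_axis), ncol = length(x_axis))
  px <- rep(x_axis, each = length(y_axis))
  py <- rep(y_axis, times = length(x_axis))
  for (poly in land) {
    land_mask <- land_mask | matrix(points_in_polygon(px, py, poly),
                                    nrow = length(y_axis))
  }

  structure(list(
    bbox = c(xmin = 0, xmax = xmax, ymin = 0, ymax = ymax),
    x_axis = x_axis, y_axis = y_axis, dx = dx,
    land = land, spawning_region = spawning, strait_region = strait,
    gates = gates, coasts = coasts, segments = segments,
    segment_length = segment_length,
    land_mask = land_mask, config = config
  ), class = "strait_domain")
}

#' @export
print.strait_domain <- function(x, ...) {
  cat("<strait_domain> ", x$bbox[["xmax"]] / 1000, "x", x$bbox[["ymax"]] / 1000,
      "km, ", length(x$land), "land polygons,",
      length(x$segments), "coastal segments\n")
  invisible(x)
}

#' Cut a coastline polyline into fixed-length segments
#'
#' Segments have exactly `segment_length` metres of coastline each except
#' possibly the last; their concatenation reproduces the input polyline and
#' ids are numbered from the polyline origin in its stated direction.
#'
#' @param polyline Two-column (x, y) matrix of ordered coastline points.
#' @param segment_length Target length, metres.
#' @param id_prefix Prefix for segment ids (e.g. `"Sic"`).
#' @param coast Coast label carried by each segment.
#' @return A list of `coastal_segment` objects (id, coast, polyline, length,
#'   and arc-length range `s_start`/`s_end` along the coast).
#' @export
segment_coastline <- function(polyline, segment_length, id_prefix = "Seg",
                              coast = NA_character_) {
  stopifnot(is.matrix(polyline), ncol(polyline) == 2)
  if (nrow(polyline) < 2) stop("empty polyline", call. = FALSE)
  if (segment_length <= 0) stop("segment_length must be > 0", call. = FALSE)
  total <- polyline_cumlength(polyline)
  total_len <- total[length(total)]
  if (total_len <= 0) stop("polyline has zero length", call. = FALSE)

  n_seg <- max(1L, as.integer(ceiling(total_len / segment_length - 1e-9)))
  cuts <- pmin(seq_len(n_seg) * segment_length, total_len)
  starts <- c(0, cuts[-n_seg])
  out <- vector("list", n_seg)
  for (k in seq_len(n_seg)) {
    s0 <- starts[k]; s1 <- cuts[k]
    inner <- which(total > s0 + 1e-9 & total < s1 - 1e-9)
    pts <- rbind(polyline_point_at(polyline, s0),
                 polyline[inner, , drop = FALSE],
                 polyline_point_at(polyline, s1))
    out[[k]] <- structure(list(
      id = paste0(id_prefix, k), coast = coast,
      polyline = pts, length = s1 - s0, s_start = s0, s_end = s1
    ), class = "coastal_segment")
  }
  out
}

#' Summarise coastal segments as a data frame
#'
#' @param segments List of `coastal_segment` objects.
#' @return Data frame with id, coast, length and arc-length range.
#' @export
segment_table <- function(segments) {
  data.frame(
    id = vapply(segments, `[[`, character(1), "id"),
    coast = vapply(segments, `[[`, character(1), "coast"),
    length = vapply(segments, `[[`, numeric(1), "length"),
    s_start = vapply(segments, `[[`, numeric(1), "s_start"),
    s_end = vapply(segments, `[[`, numeric(1), "s_end"),
    stringsAsFactors = FALSE
  )
}

#' Region membership of a point
#'
#' Returns the labels of all named regions containing the position; points
#' on a region boundary count as inside. A far-field point in open water
#' returns an empty character vector.
#'
#' @param domain A `strait_domain`.
#' @param position Length-2 numeric (x, y), metres.
#' @return Character vector among `"land"`, `"spawning_region"`,
#'   `"strait_region"` (land additionally reports the specific polygon in
#'   the `"polygon"` attribute).
#' @export
locate <- function(domain, position) {
  stopifnot(inherits(domain, "strait_domain"), length(position) == 2,
            all(is.finite(position)))
  labs <- character(0)
  hit_poly <- NA_character_
  for (nm in names(domain$land)) {
    if (points_in_polygon(position[1], position[2], domain$land[[nm]])) {
      labs <- c(labs, "land"); hit_poly <- nm; break
    }
  }
  if (points_in_polygon(position[1], position[2], domain$spawning_region)) {
    labs <- c(labs, "spawning_region")
  }
  if (points_in_polygon(position[1], position[2], domain$strait_region)) {
    labs <- c(labs, "strait_region")
  }
  attr(labs, "polygon") <- hit_poly
  labs
}

#' Detect a stranding event along a particle displacement
#'
#' Intersects the displacement segment `prev_position -> new_position` with
#' every land-polygon edge and reports the first crossing in path order:
#' the contacted coast, the nearest 5-km coastal segment (mainland coasts
#' only), the contact point and its arc length along the coastline.
#'
#' @param domain A `strait_domain`.
#' @param prev_position,new_position Length-2 numeric positions, metres;
#'   `prev_position` must be in water.
#' @return `NULL` if the path stays in water, else a list with elements
#'   `coast` (`"sicily"`, `"calabria"` or `"island:<name>"`), `segment_id`
#'   (`NA` for islands), `point`, `s` (arc length, `NA` for islands) and
#'   `path_frac` (parametric position of the contact along the step).
#' @export
detect_stranding <- function(domain, prev_position, new_position) {
  stopifnot(inherits(domain, "strait_domain"))
  best_u <- Inf; best_poly <- NA_character_
  for (nm in names(domain$land)) {
    poly <- domain$land[[nm]]
    n <- nrow(poly); j <- n
    for (i in seq_len(n)) {
      u <- segment_crossing_param(prev_position[1], prev_position[2],
                                  new_position[1], new_position[2],
                                  poly[j, 1], poly[j, 2], poly[i, 1], poly[i, 2])
      if (!is.na(u) && u < best_u) { best_u <- u; best_poly <- nm }
      j <- i
    }
  }
  if (!is.finite(best_u)) return(NULL)
  contact <- prev_position + best_u * (new_position - prev_position)
  stranding_record(domain, contact, best_poly, best_u)
}

# Shared contact -> (coast, segment, arclength) mapping.
stranding_record <- function(domain, contact, poly_name, path_frac) {
  if (startsWith(poly_name, "island:")) {
    return(list(coast = poly_name, segment_id = NA_character_,
                point = as.numeric(contact), s = NA_real_, path_frac = path_frac))
  }
  coast <- sub("_side$", "", poly_name)
  proj <- polyline_project(domain$coasts[[coast]], contact[1], contact[2])
  seg_tab <- segment_table(domain$segments)
  seg_tab <- seg_tab[seg_tab$coast == coast, , drop = FALSE]
  idx <- which(proj$s <= seg_tab$s_end + 1e-9 & proj$s >= seg_tab$s_start - 1e-9)[1]
  if (is.na(idx)) idx <- nrow(seg_tab)
  list(coast = coast, segment_id = seg_tab$id[idx],
       point = as.numeric(contact), s = proj$s, path_frac = path_frac)
}

#' Classify a gate exit from the strait
#'
#' For a particle previously inside the strait region, reports which gate
#' half-plane the position has crossed.
#'
#' @param domain A `strait_domain`.
#' @param position Length-2 numeric (x, y), metres.
#' @return `"tyrrhenian"`, `"ionian"` or `"none"`.
#' @export
classify_exit <- function(domain, position) {
  stopifnot(inherits(domain, "strait_domain"))
  if (position[2] > domain$gates$tyrrhenian$y) return("tyrrhenian")
  if (position[2] < domain$gates$ionian$y) return("ionian")
  "none"
}
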