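#' Configuration for the idealized strait-and-basin forcing
#'
#' Bundles the physical parameters of the synthetic hydrodynamic scenario:
#' a narrow tidal channel (the strait) joining a southern open sea to a
#' northern basin holding an island archipelago, with
#' \itemize{
#'   \item a semi-diurnal along-channel tidal jet peaked at the sill
#'     (peak speed above 2 m/s, M2 period 44712 s by default),
#'   \item a southward residual through-flow of 0.2--0.3 m/s with an
#'     anticyclonic (clockwise) recirculation cell just north of the sill,
#'   \item a weak (5--10 cm/s) southeastward basin drift around the islands,
#'     funnelled into the strait mouth by a convergent inflow patch, and
#'   \item a spatially uniform wind series whose direction is drawn monthly
#'     from a north-westerly-dominated prevalence table.
#' }
#'
#' @param tidal_period Semi-diurnal period, seconds (default M2 = 44712).
#' @param tidal_peak_speed Peak along-channel tidal speed at the sill, m/s.
#' @param residual_speed Residual through-flow speed in the channel, m/s.
#' @param basin_speed Basin drift speed, m/s.
#' @param eddy_centre Centre (x, y) of the recirculation cell, metres.
#' @param eddy_radius Radius of peak tangential speed of the cell, metres.
#' @param eddy_peak_speed Peak tangential speed of the cell, m/s;
#'   defaults to `residual_speed`.
#' @param wind_nw_prevalence Length-12 vector, monthly probability of
#'   north-westerly wind (the remaining probability is spread uniformly over
#'   the other seven compass sectors). Defaults follow the annual ~50%
#'   NW prevalence with a May maximum of 95%, 80% in June and an October
#'   minimum of 8%.
#' @param wind_prevalence Optional full 12 x 8 prevalence matrix (rows =
#'   months, columns = N, NE, E, SE, S, SW, W, NW); rows must sum to 1.
#'   Overrides `wind_nw_prevalence`.
#' @param wind_speed_shape,wind_speed_scale Weibull parameters of the wind
#'   speed distribution (m/s); the scale may be 0 for calm runs.
#' @param wind_interval Wind sampling interval, seconds.
#' @param grid_spacing Grid cell size, metres.
#' @param domain_size Domain extent (x, y), metres.
#' @param channel_x Western/eastern channel wall positions, metres.
#' @param mouth_y Latitude (y) of the channel mouth into the basin, metres.
#' @param sill_y Latitude of the sill (tidal jet maximum), metres.
#' @param tidal_decay_length Along-channel Gaussian decay scale of the tidal
#'   amplitude about the sill, metres.
#' @param gate_y Named vector `c(ionian=, tyrrhenian=)`: latitudes of the two
#'   cross-channel gates bounding the strait region, metres.
#' @param basin_drift_heading Compass heading (degrees) toward which the
#'   basin water drifts (135 = southeastward).
#' @param spawning_box Spawning region `c(xmin, xmax, ymin, ymax)`, metres.
#' @param islands Named list of `list(centre=c(x, y), radius=)` describing
#'   the archipelago.
#' @param rng_seed Optional default seed used by [make_wind_series()].
#'
#' @return An object of class `flow_config` (a validated list).
#' @seealso [make_idealized_domain()], [make_strait_field()],
#'   [make_wind_series()]
#' @export
flow_config <- function(tidal_period = 44712,
                        tidal_peak_speed = 2.2,
                        residual_speed = 0.25,
                        basin_speed = 0.08,
                        eddy_centre = c(30000, 19000),
                        eddy_radius = 2000,
                        eddy_peak_speed = NULL,
                        wind_nw_prevalence = c(0.50, 0.50, 0.55, 0.60, 0.95, 0.80,
                                               0.35, 0.30, 0.30, 0.08, 0.40, 0.45),
                        wind_prevalence = NULL,
                        wind_speed_shape = 2,
                        wind_speed_scale = 6,
                        wind_interval = 3600,
                        grid_spacing = 500,
                        domain_size = c(60000, 80000),
                        channel_x = c(27000, 33000),
                        mouth_y = 35000,
                        sill_y = 15000,
                        tidal_decay_length = 8000,
                        gate_y = c(ionian = 4000, tyrrhenian = 33000),
                        basin_drift_heading = 135,
                        spawning_box = c(8000, 28000, 44000, 70000),
                        islands = NULL,
                        rng_seed = NULL) {
  if (is.null(eddy_peak_speed)) eddy_peak_speed <- residual_speed
  if (is.null(islands)) {
    islands <- list(
      lipari    = list(centre = c(17000, 56000), radius = 2800),
      vulcano   = list(centre = c(19500, 49500), radius = 2200),
      salina    = list(centre = c(13000, 61000), radius = 2400),
      panarea   = list(centre = c(22500, 62500), radius = 1400),
      stromboli = list(centre = c(26500, 69000), radius = 1800)
    )
  }
  speeds <- c(tidal_peak_speed, residual_speed, basin_speed, eddy_peak_speed)
  if (any(!is.finite(speeds)) || any(speeds < 0)) {
    stop("all configured speeds must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(tidal_period) || tidal_period <= 0) {
    stop("tidal_period must be > 0", call. = FALSE)
  }
  if (grid_spacing <= 0) stop("grid_spacing must be > 0", call. = FALSE)
  if (diff(channel_x) <= 2 * grid_spacing) {
    stop("degenerate geometry: channel width must exceed 2 grid cells", call. = FALSE)
  }
  if (is.null(wind_prevalence)) {
    if (length(wind_nw_prevalence) != 12 ||
        any(wind_nw_prevalence < 0 | wind_nw_prevalence > 1)) {
      stop("wind_nw_prevalence must be 12 probabilities in [0, 1]", call. = FALSE)
    }
    wind_prevalence <- t(vapply(wind_nw_prevalence, function(p) {
      row <- rep((1 - p) / 7, 8)
      row[8] <- p
      row
    }, numeric(8)))
    colnames(wind_prevalence) <- compass_sectors()
  } else {
    wind_prevalence <- as.matrix(wind_prevalence)
    if (!all(dim(wind_prevalence) == c(12, 8))) {
      stop("wind_prevalence must be a 12 x 8 matrix", call. = FALSE)
    }
    if (is.null(colnames(wind_prevalence))) colnames(wind_prevalence) <- compass_sectors()
  }
  rs <- rowSums(wind_prevalence)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("wind prevalence rows must each sum to 1", call. = FALSE)
  }
  wind_prevalence <- wind_prevalence / rs  # absorb serialization round-off
  if (wind_speed_shape <= 0 || wind_speed_scale < 0) {
    stop("wind speed distribution parameters must be positive (scale may be 0)",
         call. = FALSE)
  }
  for (isl in islands) {
    if (isl$centre[2] - isl$radius <= mouth_y) {
      stop("islands must lie strictly inside the basin (north of the mouth)",
           call. = FALSE)
    }
  }
  structure(list(
    tidal_period = tidal_period, tidal_peak_speed = tidal_peak_speed,
    residual_speed = residual_speed, basin_speed = basin_speed,
    eddy_centre = eddy_centre, eddy_radius = eddy_radius,
    eddy_peak_speed = eddy_peak_speed,
    wind_prevalence = wind_prevalence,
    wind_speed_shape = wind_speed_shape, wind_speed_scale = wind_speed_scale,
    wind_interval = wind_interval,
    grid_spacing = grid_spacing, domain_size = domain_size,
    channel_x = channel_x, mouth_y = mouth_y, sill_y = sill_y,
    tidal_decay_length = tidal_decay_length, gate_y = gate_y,
    basin_drift_heading = basin_drift_heading,
    spawning_box = spawning_box, islands = islands,
    rng_seed = rng_seed
  ), class = "flow_config")
}

compass_sectors <- function() c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

# Compass heading (degrees, wind *from* direction) -> unit drift vector of
# the air moving *toward* the opposite heading.
compass_to_vector <- function(deg) {
  rad <- deg * pi / 180
  c(-sin(rad), -cos(rad))
}

#' Read or write a flow configuration as YAML
#'
#' @param path File path.
#' @param config A [flow_config()] object (for writing).
#' @return `read_flow_config` returns a `flow_config`.
#' @export
read_flow_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$islands)) {
    raw$islands <- lapply(raw$islands, function(i)
      list(centre = as.numeric(i$centre), radius = as.numeric(i$radius)))
  }
  if (!is.null(raw$gate_y)) raw$gate_y <- unlist(raw$gate_y)
  if (!is.null(raw$wind_prevalence)) {
    raw$wind_prevalence <- do.call(rbind, lapply(raw$wind_prevalence, as.numeric))
  }
  do.call(flow_config, raw)
}

#' @rdname read_flow_config
#' @export
write_flow_config <- function(config, path) {
  stopifnot(inherits(config, "flow_config"))
  out <- unclass(config)
  out$wind_prevalence <- apply(out$wind_prevalence, 1, as.numeric, simplify = FALSE)
  out$gate_y <- as.list(out$gate_y)
  yaml::write_yaml(out, path)
  invisible(path)
}
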