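# Spatially uniform wind forcing and the simulation calendar.

# Simulations use an abstract 365-day year starting 1 January.
.month_start_days <- c(0, 31, 59, 90, 120, 151, 181, 212, 243, 273, 304, 334)

#' Month index (1--12) of a simulation time
#'
#' @param t Time in seconds since run start (1 January, abstract 365-day
#'   year); multi-year times wrap.
#' @return Integer month, vectorized.
#' @export
month_of_time <- function(t) {
  day <- floor(t / 86400) %% 365
  findInterval(day, .month_start_days)
}

#' Construct a wind series from explicit samples
#'
#' @param times Interval start times, seconds (uniform step).
#' @param u,v Wind velocity components, m/s (eastward / northward).
#' @param sector Optional compass-sector labels per interval.
#' @return A `wind_series`: piecewise-constant wind over each interval.
#' @export
wind_series <- function(times, u, v, sector = NULL) {
  stopifnot(length(times) == length(u), length(u) == length(v))
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || any(abs(dt - dt[1]) > 1e-6)) {
      stop("wind times must be strictly increasing with uniform step", call. = FALSE)
    }
    interval <- dt[1]
  } else {
    interval <- Inf
  }
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    stop("wind speeds must be finite", call. = FALSE)
  }
  structure(list(times = times, interval = interval, u = u, v = v,
                 sector = sector), class = "wind_series")
}

#' Generate the stochastic wind series
#'
#' Each interval draws a compass sector from the month's prevalence row and
#' a speed from the configured Weibull distribution; the velocity vector
#' points away from the sector the wind blows from (a NW wind drives
#' drift toward the southeast).
#'
#' @param config A [flow_config()].
#' @param duration Series length, seconds.
#' @param seed Optional RNG seed (defaults to `config$rng_seed`); the same
#'   seed reproduces the identical series.
#' @return A `wind_series`.
#' @export
make_wind_series <- function(config, duration, seed = config$rng_seed) {
  stopifnot(inherits(config, "flow_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(ceiling(duration / config$wind_interval))
  times <- (seq_len(n) - 1) * config$wind_interval
  months <- month_of_time(times)
  sectors <- character(n)
  for (m in sort(unique(months))) {
    idx <- months == m
    sectors[idx] <- sample(compass_sectors(), sum(idx), replace = TRUE,
                           prob = config$wind_prevalence[m, ])
  }
  speed <- if (config$wind_speed_scale > 0) {
    stats::rweibull(n, shape = config$wind_speed_shape,
                    scale = config$wind_speed_scale)
  } else {
    numeric(n)
  }
  deg <- c(N = 0, NE = 45, E = 90, SE = 135, S = 180, SW = 225, W = 270, NW = 315)
  rad <- deg[sectors] * pi / 180
  wind_series(times, u = -speed * sin(rad), v = -speed * cos(rad),
              sector = sectors)
}

#' Wind velocity at a time
#'
#' @param wind A `wind_series` (or `NULL` for calm).
#' @param t Time, seconds.
#' @return Numeric `c(u, v)` in m/s.
#' @export
wind_at <- function(wind, t) {
  if (is.null(wind)) return(c(0, 0))
  k <- if (is.finite(wind$interval)) {
    floor((t - wind$times[1]) / wind$interval) + 1
  } else 1
  k <- min(max(k, 1), length(wind$u))
  c(wind$u[k], wind$v[k])
}
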