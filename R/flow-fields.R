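# Gridded flow fields.
#
# Two internal representations share one interface:
#   * "harmonic"  -- residual pattern plus a tidal-amplitude pattern
#                    oscillating as cos(2*pi*t/period); compact enough for
#                    year-long runs at hourly output.
#   * "snapshots" -- u, v arrays indexed (time, y, x) with linear time
#                    interpolation, for externally supplied fields.
# Space interpolation is bilinear with land cells excluded from the stencil
# (weights renormalized over water corners) so coastal velocities are not
# artificially dragged toward zero.

new_flow_field <- function(type, x, y, land_mask, t_end, extra) {
  stopifnot(length(x) > 1, length(y) > 1)
  dx <- diff(x); dy <- diff(y)
  if (any(abs(dx - dx[1]) > 1e-6) || any(abs(dy - dy[1]) > 1e-6)) {
    stop("grid axes must be uniformly spaced", call. = FALSE)
  }
  if (dx[1] <= 0 || dy[1] <= 0) stop("grid spacing must be > 0", call. = FALSE)
  structure(c(list(type = type, x = x, y = y, dx = dx[1], dy = dy[1],
                   land_mask = land_mask, t_start = 0, t_end = t_end), extra),
            class = "flow_field")
}

#' Construct a flow field from explicit snapshots
#'
#' @param x,y Cell-centre axes, metres (uniform spacing).
#' @param times Snapshot times, seconds, strictly increasing.
#' @param u,v Arrays of dimension `(time, y, x)`, m/s.
#' @param land_mask Logical `(y, x)` matrix, `TRUE` on land.
#' @return A `flow_field`.
#' @export
flow_field_snapshots <- function(x, y, times, u, v, land_mask = NULL) {
  if (is.null(land_mask)) land_mask <- matrix(FALSE, length(y), length(x))
  stopifnot(all(dim(u) == c(length(times), length(y), length(x))),
            all(dim(v) == dim(u)), all(diff(times) > 0))
  for (k in seq_along(times)) {
    uk <- u[k, , ]; vk <- v[k, , ]
    if (any(!is.finite(uk[!land_mask])) || any(!is.finite(vk[!land_mask]))) {
      stop("velocities must be finite at water cells", call. = FALSE)
    }
    uk[land_mask] <- 0; vk[land_mask] <- 0
    u[k, , ] <- uk; v[k, , ] <- vk
  }
  new_flow_field("snapshots", x, y, land_mask, t_end = times[length(times)],
                 list(times = times, u = u, v = v))
}

flow_field_harmonic <- function(x, y, u_res, v_res, u_amp, v_amp, period,
                                land_mask = NULL, t_end = Inf) {
  if (is.null(land_mask)) land_mask <- matrix(FALSE, length(y), length(x))
  for (m in list(u_res, v_res, u_amp, v_amp)) {
    stopifnot(all(dim(m) == c(length(y), length(x))))
    if (any(!is.finite(m[!land_mask]))) {
      stop("velocities must be finite at water cells", call. = FALSE)
    }
  }
  z <- function(m) { m[land_mask] <- 0; m }
  new_flow_field("harmonic", x, y, land_mask, t_end = t_end,
                 list(u_res = z(u_res), v_res = z(v_res),
                      u_amp = z(u_amp), v_amp = z(v_amp), period = period))
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field:", x$type, "> grid", length(x$x), "x", length(x$y),
      " dx =", x$dx, "m, coverage [0,", x$t_end, "] s\n")
  invisible(x)
}

# Land-aware bilinear interpolation of one or more layers at (px, py).
# Returns a list of interpolated vectors, one per layer.
bilinear_layers <- function(field, px, py, layers) {
  nx <- length(field$x); ny <- length(field$y)
  fx <- (px - field$x[1]) / field$dx
  fy <- (py - field$y[1]) / field$dy
  i0 <- pmin(pmax(floor(fx), 0), nx - 2)
  j0 <- pmin(pmax(floor(fy), 0), ny - 2)
  tx <- pmin(pmax(fx - i0, 0), 1)
  ty <- pmin(pmax(fy - j0, 0), 1)
  i0 <- i0 + 1L; j0 <- j0 + 1L  # 1-based lower corner
  water <- !field$land_mask
  idx00 <- cbind(j0, i0); idx01 <- cbind(j0, i0 + 1L)
  idx10 <- cbind(j0 + 1L, i0); idx11 <- cbind(j0 + 1L, i0 + 1L)
  w00 <- (1 - tx) * (1 - ty) * water[idx00]
  w01 <- tx * (1 - ty) * water[idx01]
  w10 <- (1 - tx) * ty * water[idx10]
  w11 <- tx * ty * water[idx11]
  wsum <- w00 + w01 + w10 + w11
  safe <- wsum > 0
  lapply(layers, function(m) {
    v <- w00 * m[idx00] + w01 * m[idx01] + w10 * m[idx10] + w11 * m[idx11]
    out <- numeric(length(px))
    out[safe] <- v[safe] / wsum[safe]
    out
  })
}

#' Evaluate field velocity at positions and time
#'
#' @param field A `flow_field`.
#' @param px,py Position vectors, metres.
#' @param t Time, seconds (scalar).
#' @return List with numeric vectors `u` and `v` (m/s).
#' @export
eval_velocity <- function(field, px, py, t) {
  stopifnot(inherits(field, "flow_field"), length(t) == 1)
  if (t < field$t_start - 1e-6 || t > field$t_end + 1e-6) {
    stop("time ", t, " outside field coverage [", field$t_start, ", ",
         field$t_end, "]", call. = FALSE)
  }
  if (field$type == "harmonic") {
    ph <- if (field$period > 0) cos(2 * pi * t / field$period) else 0
    vals <- bilinear_layers(field, px, py,
                            list(field$u_res, field$v_res, field$u_amp, field$v_amp))
    u <- vals[[1]] + ph * vals[[3]]
    v <- vals[[2]] + ph * vals[[4]]
  } else {
    times <- field$times
    k <- findInterval(t, times, all.inside = TRUE)
    f <- (t - times[k]) / (times[k + 1] - times[k])
    f <- min(max(f, 0), 1)
    vals <- bilinear_layers(field, px, py,
                            list(field$u[k, , ], field$v[k, , ],
                                 field$u[k + 1, , ], field$v[k + 1, , ]))
    u <- (1 - f) * vals[[1]] + f * vals[[3]]
    v <- (1 - f) * vals[[2]] + f * vals[[4]]
  }
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    stop("non-finite velocity at a water point", call. = FALSE)
  }
  list(u = u, v = v)
}

#' Generate the idealized strait flow field
#'
#' Builds the harmonic forcing field on the domain grid: the southward
#' residual through-flow in the channel (suppressed inside the
#' recirculation cell so the cell's own clockwise rotation dominates
#' there), the convergent inflow patch at the mouth, the southeastward
#' basin drift, and the semi-diurnal tidal jet peaked at the sill. Land
#' cells carry zero velocity.
#'
#' @param config A [flow_config()].
#' @param domain A `strait_domain` from [make_idealized_domain()].
#' @param duration Field time coverage, seconds; at least one tidal period.
#' @return A `flow_field` of type `"harmonic"`.
#' @export
make_strait_field <- function(config, domain, duration) {
  stopifnot(inherits(config, "flow_config"), inherits(domain, "strait_domain"))
  if (duration < config$tidal_period) {
    stop("duration must cover at least one tidal period", call. = FALSE)
  }
  x <- domain$x_axis; y <- domain$y_axis
  nx <- length(x); ny <- length(y)
  X <- matrix(x, ny, nx, byrow = TRUE)
  Y <- matrix(y, ny, nx)
  cw <- config$channel_x[1]; ce <- config$channel_x[2]
  xc <- mean(config$channel_x); my <- config$mouth_y
  in_channel <- X > cw & X < ce & Y <= my

  u_res <- matrix(0, ny, nx); v_res <- matrix(0, ny, nx)

  # Recirculation cell: clockwise, tangential speed peaking at eddy_radius.
  ex <- config$eddy_centre[1]; ey <- config$eddy_centre[2]
  R <- config$eddy_radius
  r <- sqrt((X - ex)^2 + (Y - ey)^2)
  vt <- config$eddy_peak_speed * (r / R) * exp(0.5 * (1 - (r / R)^2))
  rr <- pmax(r, 1e-9)
  u_res <- u_res + vt * (Y - ey) / rr
  v_res <- v_res - vt * (X - ex) / rr

  # Channel through-flow, suppressed within the cell so the time-mean speed
  # at the cell rim equals the configured eddy tangential speed.
  suppress <- 1 - pmin(1, exp(1 - (r / R)^2))
  v_res[in_channel] <- v_res[in_channel] -
    config$residual_speed * suppress[in_channel]

  # Convergent inflow at the mouth funnels basin water into the channel.
  basin <- Y > my
  inflow <- -config$residual_speed *
    exp(-((Y - my) / 4000)^2 - ((X - xc) / 3500)^2)
  v_res[basin] <- v_res[basin] + inflow[basin]

  # Weak basin drift toward the configured compass heading.
  dirv <- compass_to_vector((config$basin_drift_heading + 180) %% 360)
  u_res[basin] <- u_res[basin] + config$basin_speed * dirv[1]
  v_res[basin] <- v_res[basin] + config$basin_speed * dirv[2]

  # Semi-diurnal tidal jet: along-channel, Gaussian about the sill.
  u_amp <- matrix(0, ny, nx)
  v_amp <- matrix(0, ny, nx)
  v_amp[in_channel] <- config$tidal_peak_speed *
    exp(-((Y[in_channel] - config$sill_y) / config$tidal_decay_length)^2)

  flow_field_harmonic(x, y, u_res, v_res, u_amp, v_amp,
                      period = config$tidal_period,
                      land_mask = domain$land_mask, t_end = duration)
}

#' Analytic oracle fields for tracker verification
#'
#' @param kind One of `"uniform"`, `"solid_rotation"`, `"double_gyre"`.
#' @param params Named list: `uniform` needs `u`, `v`; `solid_rotation`
#'   needs `centre`, `omega` (rad/s); `double_gyre` needs `psi0`
#'   (streamfunction amplitude, m^2/s) and uses the grid extent as the
#'   two-cell domain.
#' @param grid List with numeric axes `x` and `y` (cell centres, metres).
#' @param t_end Time coverage, seconds.
#' @return A static `flow_field` (zero tidal amplitude).
#' @export
make_analytic_field <- function(kind, params, grid, t_end = Inf) {
  x <- grid$x; y <- grid$y
  nx <- length(x); ny <- length(y)
  X <- matrix(x, ny, nx, byrow = TRUE)
  Y <- matrix(y, ny, nx)
  zero <- matrix(0, ny, nx)
  uv <- switch(kind,
    uniform = {
      stopifnot(is.numeric(params$u), is.numeric(params$v))
      list(u = zero + params$u, v = zero + params$v)
    },
    solid_rotation = {
      stopifnot(length(params$centre) == 2, is.numeric(params$omega))
      list(u = -params$omega * (Y - params$centre[2]),
           v = params$omega * (X - params$centre[1]))
    },
    double_gyre = {
      stopifnot(is.numeric(params$psi0))
      Lx <- max(x) - min(x); Ly <- max(y) - min(y)
      xs <- (X - min(x)) / Lx; ys <- (Y - min(y)) / Ly
      list(u = params$psi0 * (pi / Ly) * sin(2 * pi * xs) * cos(pi * ys),
           v = -params$psi0 * (2 * pi / Lx) * cos(2 * pi * xs) * sin(pi * ys))
    },
    stop("unknown analytic field kind: ", kind, call. = FALSE)
  )
  flow_field_harmonic(x, y, uv$u, uv$v, zero, zero, period = 0, t_end = t_end)
}

#' Sample a field onto explicit snapshots
#'
#' @param field A `flow_field`.
#' @param times Snapshot times, seconds.
#' @return A `flow_field` of type `"snapshots"` with `u`, `v` indexed
#'   `(time, y, x)`.
#' @export
as_snapshot_field <- function(field, times) {
  stopifnot(inherits(field, "flow_field"))
  ny <- length(field$y); nx <- length(field$x)
  u <- array(0, c(length(times), ny, nx))
  v <- array(0, c(length(times), ny, nx))
  X <- rep(field$x, each = ny); Y <- rep(field$y, nx)
  for (k in seq_along(times)) {
    if (field$type == "harmonic") {
      ph <- if (field$period > 0) cos(2 * pi * times[k] / field$period) else 0
      u[k, , ] <- field$u_res + ph * field$u_amp
      v[k, , ] <- field$v_res + ph * field$v_amp
    } else {
      vel <- eval_velocity(field, X, Y, times[k])
      u[k, , ] <- matrix(vel$u, ny, nx)
      v[k, , ] <- matrix(vel$v, ny, nx)
    }
  }
  flow_field_snapshots(field$x, field$y, times, u, v, field$land_mask)
}
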