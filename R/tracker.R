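#' Tracker configuration
#'
#' @param dt Integration time step, seconds.
#' @param windage_alpha Fraction of wind speed imparted to drift
#'   (default 0.004, i.e. 4 per mille).
#' @param diffusivity Horizontal eddy diffusivity K, m^2/s; 0 disables the
#'   random walk.
#' @param integrator `"euler"`, `"rk2"` or `"rk4"` for the deterministic part.
#' @param output_interval Position recording interval, seconds; must be a
#'   multiple of `dt`.
#' @param land_interaction `"absorb"` (stranding is terminal) or `"reflect"`
#'   (specular reflection off the coastline).
#' @return A `tracker_config` list.
#' @export
tracker_config <- function(dt = 300, windage_alpha = 0.004, diffusivity = 5,
                           integrator = c("rk4", "rk2", "euler"),
                           output_interval = 3600,
                           land_interaction = c("absorb", "reflect")) {
  integrator <- match.arg(integrator)
  land_interaction <- match.arg(land_interaction)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (windage_alpha < 0 || windage_alpha > 1) {
    stop("windage_alpha must be in [0, 1]", call. = FALSE)
  }
  if (diffusivity < 0) stop("diffusivity must be >= 0", call. = FALSE)
  if (abs(output_interval / dt - round(output_interval / dt)) > 1e-9) {
    stop("output_interval must be a multiple of dt", call. = FALSE)
  }
  structure(list(dt = dt, windage_alpha = windage_alpha,
                 diffusivity = diffusivity, integrator = integrator,
                 output_interval = output_interval,
                 land_interaction = land_interaction),
            class = "tracker_config")
}

#' Release schedule for an experiment
#'
#' @param region Two-column polygon matrix particles are seeded in
#'   (uniformly over its water portion).
#' @param start_time,end_time Seeding window, seconds since run start.
#' @param release_interval Time between release pulses, seconds (default
#'   semi-diurnal, 44712 s).
#' @param particles_per_release Particles seeded per pulse.
#' @return A `release_schedule` list.
#' @export
release_schedule <- function(region, start_time, end_time,
                             release_interval = 44712,
                             particles_per_release = 1) {
  stopifnot(is.matrix(region), ncol(region) == 2)
  if (start_time >= end_time) stop("start_time must precede end_time", call. = FALSE)
  if (particles_per_release < 1) {
    stop("particles_per_release must be >= 1", call. = FALSE)
  }
  structure(list(region = region, start_time = start_time,
                 end_time = end_time, release_interval = release_interval,
                 particles_per_release = as.integer(particles_per_release)),
            class = "release_schedule")
}

#' Seed positions uniformly over the water portion of a region
#'
#' Rejection sampling over the region's bounding box, discarding land and
#' out-of-region draws.
#'
#' @param domain A `strait_domain`.
#' @param region Two-column polygon matrix.
#' @param n Number of positions.
#' @return An `n x 2` matrix of (x, y) positions, all in water.
#' @export
seed_uniform <- function(domain, region, n) {
  stopifnot(inherits(domain, "strait_domain"), n >= 1)
  bb <- c(range(region[, 1]), range(region[, 2]))
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  tries <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 100L)
    cx <- stats::runif(m, bb[1], bb[2])
    cy <- stats::runif(m, bb[3], bb[4])
    ok <- points_in_polygon(cx, cy, region)
    for (poly in domain$land) {
      if (!any(ok)) break
      ok[ok] <- !points_in_polygon(cx[ok], cy[ok], poly)
    }
    k <- which(ok)
    if (length(k)) {
      take <- k[seq_len(min(length(k), n - got))]
      out[(got + 1):(got + length(take)), ] <- cbind(cx[take], cy[take])
      got <- got + length(take)
    }
    tries <- tries + 1L
    if (tries > 1000L) {
      stop("release region appears to contain no water", call. = FALSE)
    }
  }
  out
}

#' Advance particles one time step (reference implementation)
#'
#' Pure-R single step: deterministic displacement by the configured
#' integrator on the interpolated currents-plus-windage velocity, then an
#' independent per-axis Gaussian random-walk increment of standard
#' deviation `sqrt(2 * K * dt)`. With `K = 0` and a uniform field the
#' displacement is exactly `(u + alpha * w) * dt`.
#'
#' @param position Length-2 vector or `n x 2` matrix of positions, metres.
#' @param time Current time, seconds.
#' @param field A `flow_field` covering `[time, time + dt]`.
#' @param wind Optional `wind_series`.
#' @param config A [tracker_config()].
#' @return Matrix of new positions (`n x 2`).
#' @export
step_particles <- function(position, time, field, wind = NULL,
                           config = tracker_config()) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  dt <- config$dt
  if (time + dt > field$t_end + 1e-6) {
    stop("time outside field coverage", call. = FALSE)
  }
  vel <- function(px, py, t) {
    v <- eval_velocity(field, px, py, t)
    w <- wind_at(wind, t)
    list(u = v$u + config$windage_alpha * w[1],
         v = v$v + config$windage_alpha * w[2])
  }
  x <- pos[, 1]; y <- pos[, 2]
  k1 <- vel(x, y, time)
  new <- switch(config$integrator,
    euler = cbind(x + dt * k1$u, y + dt * k1$v),
    rk2 = {
      k2 <- vel(x + 0.5 * dt * k1$u, y + 0.5 * dt * k1$v, time + dt / 2)
      cbind(x + dt * k2$u, y + dt * k2$v)
    },
    rk4 = {
      k2 <- vel(x + 0.5 * dt * k1$u, y + 0.5 * dt * k1$v, time + dt / 2)
      k3 <- vel(x + 0.5 * dt * k2$u, y + 0.5 * dt * k2$v, time + dt / 2)
      k4 <- vel(x + dt * k3$u, y + dt * k3$v, time + dt)
      cbind(x + dt / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u),
            y + dt / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v))
    }
  )
  if (config$diffusivity > 0) {
    sd <- sqrt(2 * config$diffusivity * dt)
    new <- new + cbind(stats::rnorm(nrow(new), 0, sd),
                       stats::rnorm(nrow(new), 0, sd))
  }
  colnames(new) <- c("x", "y")
  new
}

# --- internal plumbing for the compiled tracker ------------------------------

field_spec_cpp <- function(field) {
  water <- matrix(as.integer(!field$land_mask), nrow(field$land_mask))
  base <- list(x0 = field$x[1], y0 = field$y[1], dx = field$dx, dy = field$dy,
               nx = length(field$x), ny = length(field$y), water = water)
  if (field$type == "harmonic") {
    c(base, list(type = 0L, u_res = field$u_res, v_res = field$v_res,
                 u_amp = field$u_amp, v_amp = field$v_amp,
                 period = field$period))
  } else {
    c(base, list(type = 1L, times = field$times,
                 u = as.numeric(field$u), v = as.numeric(field$v)))
  }
}

wind_spec_cpp <- function(wind, alpha) {
  if (is.null(wind) || alpha <= 0) return(list(active = FALSE))
  list(active = TRUE, t0 = wind$times[1],
       dt = if (is.finite(wind$interval)) wind$interval else 1e18,
       u = wind$u, v = wind$v)
}

# Edge table of all land polygons: columns x1, y1, x2, y2; names per edge.
domain_edges <- function(domain) {
  mats <- list(); labels <- character(0)
  for (nm in names(domain$land)) {
    poly <- domain$land[[nm]]
    nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
    mats[[nm]] <- cbind(poly, nxt)
    labels <- c(labels, rep(nm, nrow(poly)))
  }
  list(edges = do.call(rbind, mats), poly = labels)
}

max_field_speed <- function(field) {
  if (field$type == "harmonic") {
    max(sqrt((abs(field$u_res) + abs(field$u_amp))^2 +
             (abs(field$v_res) + abs(field$v_amp))^2))
  } else {
    max(sqrt(field$u^2 + field$v^2))
  }
}

# Coarse flag grid marking land cells and a coastal band wide enough that a
# particle cannot jump across it in one sub-step.
near_coast_band <- function(domain, edges, band_dist) {
  res <- domain$dx
  cx <- domain$x_axis; cy <- domain$y_axis
  PX <- rep(cx, each = length(cy)); PY <- rep(cy, times = length(cx))
  near <- rep(FALSE, length(PX))
  reach <- band_dist + res * sqrt(2) / 2
  for (i in seq_len(nrow(edges))) {
    d <- point_segment_distance(PX, PY, edges[i, 1], edges[i, 2],
                                edges[i, 3], edges[i, 4])
    near <- near | (d <= reach)
  }
  flag <- matrix(near, nrow = length(cy)) | domain$land_mask
  list(flag = matrix(as.integer(flag), nrow = length(cy)),
       x0 = domain$bbox[["xmin"]], y0 = domain$bbox[["ymin"]], dx = res)
}

#' Run a seeded tracking experiment
#'
#' Releases particles per the schedule, advects them through the field with
#' windage and diffusion, resolves stranding geometrically at every
#' sub-step, and records hourly positions, first strait entry, gate exits
#' and domain loss. Every particle ends in exactly one of the statuses
#' `active`, `stranded`, `exited_tyrrhenian`, `exited_ionian`,
#' `left_domain`.
#'
#' @param field A `flow_field` covering `[0, duration]`.
#' @param wind Optional `wind_series`.
#' @param domain A `strait_domain`.
#' @param schedule A [release_schedule()].
#' @param config A [tracker_config()].
#' @param duration Run length, seconds.
#' @param seed RNG seed (governs seeding and diffusion).
#' @param record `"all"` to keep every hourly position, `"strait"` to keep
#'   only positions inside the strait region, `"none"` for terminal
#'   summaries only.
#' @return A `trajectory_set`: list with `particles` (one row per particle:
#'   source position, release time, cohort, status, status time, first
#'   strait-entry time, stranding coast/segment/arc-length, final position)
#'   and `positions` (long data frame id/time/x/y).
#' @export
run_experiment <- function(field, wind, domain, schedule,
                           config = tracker_config(), duration,
                           seed = 1L, record = c("all", "strait", "none")) {
  record <- match.arg(record)
  stopifnot(inherits(schedule, "release_schedule"))
  if (duration > field$t_end + 1e-6) {
    stop("field does not cover the run duration", call. = FALSE)
  }
  set.seed(seed)
  out_int <- config$output_interval
  nsub <- as.integer(round(out_int / config$dt))

  rel_times <- seq(schedule$start_time, schedule$end_time,
                   by = schedule$release_interval)
  rel_times <- round(rel_times / out_int) * out_int
  ppr <- schedule$particles_per_release
  n_total <- length(rel_times) * ppr

  ed <- domain_edges(domain)
  wind_max <- if (is.null(wind)) 0 else max(sqrt(wind$u^2 + wind$v^2), 0)
  band_dist <- (max_field_speed(field) + config$windage_alpha * wind_max) *
    config$dt + 6 * sqrt(2 * config$diffusivity * config$dt)
  band <- near_coast_band(domain, ed$edges, band_dist)
  fs <- field_spec_cpp(field)
  ws <- wind_spec_cpp(wind, config$windage_alpha)
  rect <- as.numeric(domain$bbox[c("xmin", "xmax", "ymin", "ymax")])
  land_mode <- if (config$land_interaction == "absorb") 0L else 1L
  integ <- match(config$integrator, c("euler", "rk2", "rk4")) - 1L
  sb <- domain$strait_region
  sxr <- range(sb[, 1]); syr <- range(sb[, 2])
  gate_n <- domain$gates$tyrrhenian$y
  gate_s <- domain$gates$ionian$y

  x <- numeric(n_total); y <- numeric(n_total)
  x0 <- numeric(n_total); y0 <- numeric(n_total)
  status <- rep(-1L, n_total)  # -1 unreleased, 0 active, 1..4 terminal
  status_time <- rep(NA_real_, n_total)
  release_time <- rep(NA_real_, n_total)
  cohort <- rep(NA_integer_, n_total)
  first_entry <- rep(NA_real_, n_total)
  strand_coast <- rep(NA_character_, n_total)
  strand_segment <- rep(NA_character_, n_total)
  strand_s <- rep(NA_real_, n_total)
  next_id <- 0L
  chunks <- list(); n_chunk <- 0L

  keep_positions <- function(ids, t, px, py) {
    if (record == "none" || length(ids) == 0) return()
    if (record == "strait") {
      keep <- px >= sxr[1] & px <= sxr[2] & py >= syr[1] & py <= syr[2]
      ids <- ids[keep]; px <- px[keep]; py <- py[keep]
      if (!length(ids)) return()
    }
    n_chunk <<- n_chunk + 1L
    chunks[[n_chunk]] <<- cbind(id = ids, time = t, x = px, y = py)
  }
  in_strait <- function(px, py) {
    px >= sxr[1] & px <= sxr[2] & py >= syr[1] & py <= syr[2]
  }

  n_steps <- as.integer(round(duration / out_int))
  for (k in seq_len(n_steps)) {
    t_now <- (k - 1) * out_int
    # releases due now
    due <- which(rel_times == t_now)
    for (cid in due) {
      pos <- seed_uniform(domain, schedule$region, ppr)
      ids <- next_id + seq_len(ppr)
      next_id <- next_id + ppr
      x[ids] <- pos[, 1]; y[ids] <- pos[, 2]
      x0[ids] <- pos[, 1]; y0[ids] <- pos[, 2]
      status[ids] <- 0L
      release_time[ids] <- t_now
      cohort[ids] <- cid
      ent <- in_strait(pos[, 1], pos[, 2])
      first_entry[ids[ent]] <- t_now
      keep_positions(ids, t_now, pos[, 1], pos[, 2])
    }
    act <- which(status == 0L)
    if (length(act)) {
      res <- advance_particles_cpp(x[act], y[act], t_now, nsub, config$dt,
                                   fs, ws, config$windage_alpha,
                                   config$diffusivity, integ, ed$edges,
                                   band$flag, band$x0, band$y0, band$dx,
                                   rect, land_mode)
      x[act] <- res$x; y[act] <- res$y
      str_i <- which(res$status == 1L)
      for (j in str_i) {
        p <- act[j]
        rec <- stranding_record(domain, c(res$x[j], res$y[j]),
                                ed$poly[res$edge[j]], NA_real_)
        status[p] <- 1L
        status_time[p] <- res$time[j]
        strand_coast[p] <- rec$coast
        strand_segment[p] <- rec$segment_id
        strand_s[p] <- rec$s
      }
      left_i <- which(res$status == 2L)
      if (length(left_i)) {
        p <- act[left_i]
        # a particle that had entered the strait and left through the
        # southern end within the hour exited to the Ionian, not the domain
        ion <- !is.na(first_entry[p]) & res$y[left_i] < gate_s
        status[p] <- ifelse(ion, 4L, 2L)
        status_time[p] <- res$time[left_i]
      }
      t_next <- t_now + out_int
      still <- act[res$status == 0L]
      if (length(still)) {
        ent <- is.na(first_entry[still]) & in_strait(x[still], y[still])
        first_entry[still[ent]] <- t_next
        entered <- !is.na(first_entry[still])
        ex_n <- entered & y[still] > gate_n
        ex_s <- entered & y[still] < gate_s
        status[still[ex_n]] <- 3L
        status[still[ex_s]] <- 4L
        status_time[still[ex_n | ex_s]] <- t_next
        keep <- still[!(ex_n | ex_s)]
        keep_positions(keep, t_next, x[keep], y[keep])
      }
    }
  }
  status_chr <- c("unreleased", "active", "stranded", "left_domain",
                  "exited_tyrrhenian", "exited_ionian")[status + 2L]
  particles <- data.frame(
    id = seq_len(n_total), x0 = x0, y0 = y0,
    release_time = release_time, cohort = cohort,
    status = status_chr, status_time = status_time,
    first_entry_time = first_entry,
    strand_coast = strand_coast, strand_segment = strand_segment,
    strand_s = strand_s, x_final = x, y_final = y,
    stringsAsFactors = FALSE
  )
  positions <- if (n_chunk > 0) {
    as.data.frame(do.call(rbind, chunks[seq_len(n_chunk)]))
  } else {
    data.frame(id = integer(0), time = numeric(0), x = numeric(0),
               y = numeric(0))
  }
  structure(list(particles = particles, positions = positions,
                 duration = duration, seed = seed, record = record,
                 output_interval = out_int),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set>", nrow(x$particles), "particles over",
      x$duration / 86400, "days\n")
  print(table(x$particles$status))
  invisible(x)
}

#' Particle accounting through time
#'
#' Recounts, at each output time, how many released particles are in each
#' status; `released` always equals the sum of the other columns.
#'
#' @param ts A `trajectory_set`.
#' @param times Output times to tabulate (defaults to every output interval).
#' @return Data frame with columns time, released, active, stranded,
#'   exited_tyrrhenian, exited_ionian, left_domain.
#' @export
conservation_table <- function(ts, times = NULL) {
  p <- ts$particles
  if (is.null(times)) times <- seq(0, ts$duration, by = ts$output_interval)
  out <- lapply(times, function(t) {
    rel <- !is.na(p$release_time) & p$release_time <= t
    done <- rel & !is.na(p$status_time) & p$status_time <= t &
      p$status != "active"
    st <- p$status[done]
    data.frame(time = t, released = sum(rel),
               active = sum(rel) - sum(done),
               stranded = sum(st == "stranded"),
               exited_tyrrhenian = sum(st == "exited_tyrrhenian"),
               exited_ionian = sum(st == "exited_ionian"),
               left_domain = sum(st == "left_domain"))
  })
  do.call(rbind, out)
}
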