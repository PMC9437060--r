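# Connectivity and retention metrics computed from trajectory sets.
#
# A particle counts as a strait entrant once, at its first entry; exits are
# first exits. All daily series use the simulation day d = floor(t/86400)+1
# and, for multi-year runs, averaging by day of a 365-day year.

sim_day <- function(t) floor(t / 86400) + 1

doy_average <- function(day, value) {
  doy <- (day - 1) %% 365 + 1
  agg <- tapply(value, doy, mean, na.rm = TRUE)
  data.frame(day = as.integer(names(agg)), value = as.numeric(agg),
             row.names = NULL)
}

#' Normalized Source Index over a regular source grid
#'
#' Bins release positions into regular cells, computes per cell and per
#' release cohort the ratio of particles that entered the strait to
#' particles released, averages the ratio across cohorts, and normalizes by
#' the maximum cell value so the best-connected cell scores 1.
#'
#' @param ts A `trajectory_set`.
#' @param bin_size Source cell size, metres (default 2000).
#' @param region Optional two-column polygon whose bounding box frames the
#'   grid; defaults to the bounding box of the release positions.
#' @return A `source_grid` data frame: cell centre/bounds, released and
#'   entered counts, cohort-averaged ratio and `nsi`. Cells with no
#'   releases have `NA` throughout (undefined, not zero). If no particle
#'   entered anywhere, `nsi` is all `NA` and the attribute
#'   `normalization_defined` is `FALSE`.
#' @export
compute_nsi <- function(ts, bin_size = 2000, region = NULL) {
  p <- ts$particles[!is.na(ts$particles$release_time), ]
  if (nrow(p) == 0) stop("no released particles", call. = FALSE)
  if (is.null(region)) {
    xr <- range(p$x0); yr <- range(p$y0)
  } else {
    xr <- range(region[, 1]); yr <- range(region[, 2])
  }
  nx <- max(1L, ceiling((xr[2] - xr[1]) / bin_size - 1e-9))
  ny <- max(1L, ceiling((yr[2] - yr[1]) / bin_size - 1e-9))
  ix <- pmin(pmax(floor((p$x0 - xr[1]) / bin_size), 0), nx - 1)
  iy <- pmin(pmax(floor((p$y0 - yr[1]) / bin_size), 0), ny - 1)
  cell <- iy * nx + ix + 1

  entered <- !is.na(p$first_entry_time)
  # cohort-wise entry ratio, then mean across cohorts present in the cell
  key <- interaction(cell, p$cohort, drop = TRUE)
  rel_ck <- tapply(rep(1, nrow(p)), key, sum)
  ent_ck <- tapply(as.numeric(entered), key, sum)
  cell_of <- as.integer(sub("\\..*$", "", names(rel_ck)))
  ratio_ck <- ent_ck / rel_ck
  ratio <- tapply(ratio_ck, cell_of, mean)

  all_cells <- seq_len(nx * ny)
  grid <- data.frame(
    cell = all_cells,
    x_lo = xr[1] + ((all_cells - 1) %% nx) * bin_size,
    y_lo = yr[1] + ((all_cells - 1) %/% nx) * bin_size
  )
  grid$x_hi <- grid$x_lo + bin_size
  grid$y_hi <- grid$y_lo + bin_size
  grid$cx <- (grid$x_lo + grid$x_hi) / 2
  grid$cy <- (grid$y_lo + grid$y_hi) / 2
  grid$released <- as.numeric(tapply(rep(1, nrow(p)), factor(cell, all_cells), sum))
  grid$released[is.na(grid$released)] <- 0
  grid$entered <- as.numeric(tapply(as.numeric(entered), factor(cell, all_cells), sum))
  grid$entered[is.na(grid$entered) & grid$released > 0] <- 0
  grid$ratio <- NA_real_
  grid$ratio[match(as.integer(names(ratio)), grid$cell)] <- as.numeric(ratio)

  mx <- suppressWarnings(max(grid$ratio, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) {
    grid$nsi <- NA_real_
    attr(grid, "normalization_defined") <- FALSE
  } else {
    grid$nsi <- grid$ratio / mx
    attr(grid, "normalization_defined") <- TRUE
  }
  attr(grid, "bin_size") <- bin_size
  class(grid) <- c("source_grid", "data.frame")
  grid
}

#' Mean travel time to the strait per source cell
#'
#' For source cells whose NSI exceeds the threshold, the mean age of their
#' entering particles at first strait entry.
#'
#' @param ts A `trajectory_set`.
#' @param source_grid A `source_grid` from [compute_nsi()].
#' @param nsi_threshold Cells at or below this NSI are left undefined
#'   (default 0.6).
#' @return The source grid with a `travel_time` column (seconds; `NA`
#'   where undefined).
#' @export
travel_time_map <- function(ts, source_grid, nsi_threshold = 0.6) {
  p <- ts$particles[!is.na(ts$particles$release_time), ]
  bin_size <- attr(source_grid, "bin_size")
  xr <- min(source_grid$x_lo); yr <- min(source_grid$y_lo)
  nx <- length(unique(source_grid$x_lo))
  ix <- pmin(pmax(floor((p$x0 - xr) / bin_size), 0), nx - 1)
  iy <- floor((p$y0 - yr) / bin_size)
  cell <- iy * nx + ix + 1
  age <- p$first_entry_time - p$release_time
  ok <- !is.na(age)
  mean_age <- tapply(age[ok], factor(cell[ok], source_grid$cell), mean)
  source_grid$travel_time <- as.numeric(mean_age)
  undef <- is.na(source_grid$nsi) |
    source_grid$nsi <= nsi_threshold + 1e-12
  source_grid$travel_time[undef] <- NA_real_
  source_grid
}

#' Daily cumulative strait entry ratio
#'
#' For each day: cumulative distinct entrants divided by cumulative
#' particles released minus those lost through the open boundary (the
#' denominator is the releases still within the model domain). Multi-year
#' runs are averaged by day of year.
#'
#' @param ts A `trajectory_set`.
#' @return Data frame with `day` and `ratio` (`NA` where the denominator
#'   is zero).
#' @export
entry_ratio_series <- function(ts) {
  p <- ts$particles[!is.na(ts$particles$release_time), ]
  days <- seq_len(max(1, ceiling(ts$duration / 86400)))
  rel_day <- sim_day(p$release_time)
  ent_day <- sim_day(p$first_entry_time)
  left_day <- rep(NA_real_, nrow(p))
  is_left <- p$status == "left_domain"
  left_day[is_left] <- sim_day(p$status_time[is_left])
  cum_rel <- cumsum(tabulate(rel_day, nbins = max(days)))
  cum_ent <- cumsum(tabulate(ent_day[!is.na(ent_day)], nbins = max(days)))
  cum_left <- cumsum(tabulate(left_day[!is.na(left_day)], nbins = max(days)))
  denom <- cum_rel - cum_left
  ratio <- ifelse(denom > 0, cum_ent / denom, NA_real_)
  doy_average(days, ratio)[, c("day", "value")] |>
    stats::setNames(c("day", "ratio"))
}

#' Daily strait occupancy
#'
#' Mean, over each day's hourly snapshots, of the number of particles
#' located inside the strait region.
#'
#' @param ts A `trajectory_set` with recorded positions.
#' @param domain A `strait_domain`.
#' @return Data frame with `day` and `count`.
#' @export
occupancy_series <- function(ts, domain) {
  pos <- ts$positions
  days <- seq_len(max(1, ceiling(ts$duration / 86400)))
  snaps_per_day <- 86400 / ts$output_interval
  if (nrow(pos) == 0) {
    return(data.frame(day = days, count = 0))
  }
  inside <- points_in_polygon(pos$x, pos$y, domain$strait_region)
  day <- sim_day(pos$time[inside])
  counts <- tabulate(day, nbins = max(days)) / snaps_per_day
  stats::setNames(doy_average(days, counts), c("day", "count"))
}

#' Cumulative retention ratio series
#'
#' Daily ratio of cumulative exits to the Tyrrhenian over cumulative strait
#' entrants; low values indicate retention.
#'
#' @param ts A `trajectory_set`.
#' @return Data frame with `day` and `ratio` (`NA` before the first entry).
#' @export
retention_ratio_series <- function(ts) {
  p <- ts$particles[!is.na(ts$particles$release_time), ]
  days <- seq_len(max(1, ceiling(ts$duration / 86400)))
  ent_day <- sim_day(p$first_entry_time[!is.na(p$first_entry_time)])
  exi <- p$status == "exited_tyrrhenian"
  exi_day <- sim_day(p$status_time[exi])
  cum_ent <- cumsum(tabulate(ent_day, nbins = max(days)))
  cum_exi <- cumsum(tabulate(exi_day, nbins = max(days)))
  ratio <- ifelse(cum_ent > 0, cum_exi / cum_ent, NA_real_)
  stats::setNames(doy_average(days, ratio), c("day", "ratio"))
}

#' Stranding shares per coastal segment
#'
#' Percentage of mainland stranding events per 5-km coastal segment, coast
#' totals, and the Calabria-to-Sicily stranding ratio. Island strandings
#' are tallied separately and excluded from the mainland shares.
#'
#' @param ts A `trajectory_set` (or a data frame of stranding events with
#'   columns `strand_coast` and `strand_segment`).
#' @param segments List of coastal segments (defaults drawn from `domain`).
#' @param domain Optional `strait_domain` supplying the segments.
#' @return A `stranding_shares` list: `shares` data frame (segment id,
#'   coast, count, share_pct), `coast_totals`, `coast_ratio`
#'   (Calabria/Sicily; `NA` if no Sicilian strandings), `island_count`.
#' @export
stranding_shares <- function(ts, segments = NULL, domain = NULL) {
  events <- if (inherits(ts, "trajectory_set")) {
    ts$particles[ts$particles$status == "stranded", , drop = FALSE]
  } else {
    ts
  }
  if (is.null(segments)) {
    if (is.null(domain)) stop("supply segments or a domain", call. = FALSE)
    segments <- domain$segments
  }
  seg_tab <- segment_table(segments)
  mainland <- events[events$strand_coast %in% c("sicily", "calabria"), , drop = FALSE]
  island_count <- nrow(events) - nrow(mainland)
  counts <- table(factor(mainland$strand_segment, levels = seg_tab$id))
  total <- sum(counts)
  shares <- data.frame(
    segment_id = seg_tab$id, coast = seg_tab$coast,
    count = as.integer(counts),
    share_pct = if (total > 0) 100 * as.integer(counts) / total else 0,
    stringsAsFactors = FALSE
  )
  coast_totals <- tapply(shares$count, shares$coast, sum)
  sic <- coast_totals[["sicily"]]; cal <- coast_totals[["calabria"]]
  ratio <- if (!is.na(sic) && sic > 0) cal / sic else NA_real_
  structure(list(shares = shares, coast_totals = coast_totals,
                 coast_ratio = ratio, island_count = island_count,
                 total_mainland = total),
            class = "stranding_shares")
}

#' @export
print.stranding_shares <- function(x, ...) {
  cat("<stranding_shares>", x$total_mainland, "mainland strandings;",
      "Calabria/Sicily ratio:", round(x$coast_ratio, 3), "\n")
  invisible(x)
}
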