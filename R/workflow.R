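# End-to-end experiment orchestration.
#
# The three protocols share one synthetic scenario: a 365-day abstract year
# over the idealized strait-and-basin domain.
#   exp1: seed the spawning region around the archipelago semi-diurnally
#         from day 25 to day 155; map NSI, travel times and entry ratio.
#   exp2: seed the strait region semi-diurnally all year; occupancy and
#         retention series.
#   exp3: seed the strait region semi-diurnally through June-August;
#         stranding shares per coastal segment and the coast ratio.

#' Configuration of a full experiment run
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param flow A [flow_config()].
#' @param tracker A [tracker_config()].
#' @param scale Particle-count scale factor (1 = desk scale, about 1e4
#'   particles per experiment).
#' @param seed Master RNG seed.
#' @param out_dir Optional output directory for CSV results and a run
#'   manifest.
#' @param seeding_days Length-2 day window overriding the experiment's
#'   seeding calendar (day 1 = 1 January).
#' @param particles_per_release Override of the per-pulse particle count
#'   (before scaling).
#' @param duration_days Run length override, days.
#' @param release_interval Release pulse spacing, seconds (default
#'   semi-diurnal).
#' @param wind `TRUE` to generate the stochastic wind series, `FALSE` for
#'   calm conditions, or a ready-made `wind_series`.
#' @return A `run_config` list.
#' @export
run_config <- function(experiment = c("exp1", "exp2", "exp3"),
                       flow = flow_config(), tracker = tracker_config(),
                       scale = 1, seed = 1L, out_dir = NULL,
                       seeding_days = NULL, particles_per_release = NULL,
                       duration_days = 365, release_interval = 44712,
                       wind = TRUE) {
  experiment <- match.arg(experiment)
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  defaults <- switch(experiment,
    exp1 = list(days = c(25, 155), ppr = 40),
    exp2 = list(days = c(1, 365), ppr = 15),
    exp3 = list(days = c(152, 243), ppr = 56)
  )
  if (is.null(seeding_days)) seeding_days <- defaults$days
  if (is.null(particles_per_release)) particles_per_release <- defaults$ppr
  structure(list(
    experiment = experiment, flow = flow, tracker = tracker, scale = scale,
    seed = as.integer(seed), out_dir = out_dir,
    seeding_days = seeding_days,
    particles_per_release = max(1L, as.integer(ceiling(particles_per_release * scale))),
    duration_days = duration_days, release_interval = release_interval,
    wind = wind
  ), class = "run_config")
}

run_scenario <- function(cfg, region_kind, record) {
  domain <- make_idealized_domain(cfg$flow)
  duration <- cfg$duration_days * 86400
  field <- make_strait_field(cfg$flow, domain, duration)
  wind <- if (isTRUE(cfg$wind)) {
    make_wind_series(cfg$flow, duration, seed = cfg$seed + 1L)
  } else if (inherits(cfg$wind, "wind_series")) {
    cfg$wind
  } else {
    NULL
  }
  region <- switch(region_kind, spawning = domain$spawning_region,
                   strait = domain$strait_region)
  schedule <- release_schedule(
    region = region,
    start_time = (cfg$seeding_days[1] - 1) * 86400,
    end_time = (cfg$seeding_days[2] - 1) * 86400,
    release_interval = cfg$release_interval,
    particles_per_release = cfg$particles_per_release
  )
  ts <- run_experiment(field, wind, domain, schedule, cfg$tracker, duration,
                       seed = cfg$seed, record = record)
  list(domain = domain, field = field, wind = wind, schedule = schedule,
       trajectories = ts)
}

#' Run the spawning-to-strait connectivity experiment
#'
#' @param cfg A [run_config()] with `experiment = "exp1"`.
#' @return A `connectivity_result`: the trajectory set, NSI source grid
#'   with travel times, and the daily entry-ratio series.
#' @export
run_exp1 <- function(cfg = run_config("exp1")) {
  stopifnot(cfg$experiment == "exp1")
  sc <- run_scenario(cfg, "spawning", record = "none")
  grid <- compute_nsi(sc$trajectories, region = sc$domain$spawning_region)
  grid <- travel_time_map(sc$trajectories, grid)
  entry <- entry_ratio_series(sc$trajectories)
  res <- structure(list(
    experiment = "exp1", trajectories = sc$trajectories,
    source_grid = grid, entry_ratio = entry, domain = sc$domain,
    config = cfg
  ), class = "connectivity_result")
  maybe_write_outputs(res, cfg)
  res
}

#' Run the strait retention experiment
#'
#' @param cfg A [run_config()] with `experiment = "exp2"`.
#' @return A `connectivity_result` with daily occupancy and retention
#'   series and residence-time summaries.
#' @export
run_exp2 <- function(cfg = run_config("exp2")) {
  stopifnot(cfg$experiment == "exp2")
  sc <- run_scenario(cfg, "strait", record = "strait")
  occ <- occupancy_series(sc$trajectories, sc$domain)
  ret <- retention_ratio_series(sc$trajectories)
  p <- sc$trajectories$particles
  resolved <- !is.na(p$release_time)
  residence <- ifelse(is.na(p$status_time[resolved]),
                      sc$trajectories$duration - p$release_time[resolved],
                      p$status_time[resolved] - p$release_time[resolved])
  res <- structure(list(
    experiment = "exp2", trajectories = sc$trajectories,
    occupancy = occ, retention = ret,
    mean_residence = mean(residence), domain = sc$domain, config = cfg
  ), class = "connectivity_result")
  maybe_write_outputs(res, cfg)
  res
}

#' Run the summer stranding experiment
#'
#' @param cfg A [run_config()] with `experiment = "exp3"`.
#' @return A `connectivity_result` with per-segment stranding shares and
#'   the Calabria-to-Sicily coast ratio.
#' @export
run_exp3 <- function(cfg = run_config("exp3")) {
  stopifnot(cfg$experiment == "exp3")
  sc <- run_scenario(cfg, "strait", record = "none")
  shares <- stranding_shares(sc$trajectories, domain = sc$domain)
  res <- structure(list(
    experiment = "exp3", trajectories = sc$trajectories,
    stranding = shares, domain = sc$domain, config = cfg
  ), class = "connectivity_result")
  maybe_write_outputs(res, cfg)
  res
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat("<connectivity_result:", x$experiment, ">\n")
  print(x$trajectories)
  invisible(x)
}

maybe_write_outputs <- function(res, cfg) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(cfg$out_dir, name), row.names = FALSE)
  }
  if (!is.null(res$source_grid)) wr(as.data.frame(res$source_grid), "nsi_grid.csv")
  if (!is.null(res$entry_ratio)) wr(res$entry_ratio, "entry_ratio.csv")
  if (!is.null(res$occupancy)) wr(res$occupancy, "occupancy.csv")
  if (!is.null(res$retention)) wr(res$retention, "retention.csv")
  if (!is.null(res$stranding)) wr(res$stranding$shares, "stranding_shares.csv")
  wr(conservation_table(res$trajectories,
                        times = seq(0, res$trajectories$duration, by = 86400)),
     "conservation.csv")
  manifest <- list(
    experiment = res$experiment,
    seed = cfg$seed,
    scale = cfg$scale,
    particles_per_release = cfg$particles_per_release,
    seeding_days = cfg$seeding_days,
    duration_days = cfg$duration_days,
    package_version = as.character(utils::packageVersion("medusadrift")),
    config_hash = config_hash(cfg)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

# Stable md5 of the serialized run configuration.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  clean <- cfg
  clean$out_dir <- NULL
  writeLines(jsonlite::toJSON(clean, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
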