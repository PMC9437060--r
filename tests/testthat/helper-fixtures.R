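# Shared fixtures. The default domain and strait field are built once per
# test run; the toy trajectory set is fully deterministic (no RNG) so
# metric recounts can be checked exactly.

.fixture_env <- new.env(parent = emptyenv())

fixture_domain <- function() {
  if (is.null(.fixture_env$domain)) {
    .fixture_env$domain <- make_idealized_domain(flow_config())
  }
  .fixture_env$domain
}

fixture_strait_field <- function(duration = 10 * 44712) {
  key <- paste0("field_", duration)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- make_strait_field(flow_config(), fixture_domain(),
                                             duration)
  }
  .fixture_env[[key]]
}

# Uniform all-water field on a small grid.
uniform_field <- function(u, v, t_end = Inf,
                          x = seq(250, 59750, by = 500),
                          y = seq(250, 79750, by = 500)) {
  make_analytic_field("uniform", list(u = u, v = v), list(x = x, y = y),
                      t_end = t_end)
}

# Straight-coast segments used by the toy metric fixture: two 20-km coasts
# cut into four 5-km segments each.
toy_segments <- function() {
  sic <- segment_coastline(rbind(c(0, 0), c(20000, 0)), 5000,
                           id_prefix = "Sic", coast = "sicily")
  cal <- segment_coastline(rbind(c(0, 3000), c(20000, 3000)), 5000,
                           id_prefix = "Cal", coast = "calabria")
  c(sic, cal)
}

# Hand-built 50-particle trajectory set with a known breakdown:
#  - 5 source cells (1-km bins over x in [0, 5000], single y row),
#    2 cohorts (release times 0 s and 43200 s), 5 particles per cell/cohort;
#  - per-cell entry counts (cohort1, cohort2):
#      cell1 (5,3)  cell2 (2,4)  cell3 (0,0)  cell4 (5,5)  cell5 (1,0)
#  - statuses: entrants split between Tyrrhenian/Ionian exits and in-strait
#    strandings; non-entrants split between left_domain, coastal and island
#    strandings, and still-active;
#  - hourly positions for three particles with scripted strait occupancy.
toy_trajectory_set <- function() {
  entered_per_cell <- list(c(5, 3), c(2, 4), c(0, 0), c(5, 5), c(1, 0))
  rows <- list()
  id <- 0
  for (cell in 1:5) {
    for (cohort in 1:2) {
      rel <- (cohort - 1) * 43200
      n_ent <- entered_per_cell[[cell]][cohort]
      for (j in 1:5) {
        id <- id + 1
        entered <- j <= n_ent
        age <- (1 + (id %% 5)) * 43200          # entry age when it enters
        fe <- if (entered) rel + age else NA_real_
        if (entered) {
          status <- c("exited_tyrrhenian", "exited_ionian", "stranded")[
            1 + (id %% 3)]
          st_time <- fe + 86400
        } else {
          status <- c("left_domain", "stranded", "active")[1 + (id %% 3)]
          st_time <- if (status == "active") NA_real_ else rel + 2 * 86400 + id * 3600
        }
        coast <- seg <- NA_character_
        if (status == "stranded") {
          pick <- id %% 4
          coast <- c("calabria", "sicily", "calabria", "island:toy")[pick + 1]
          seg <- c("Cal2", "Sic1", "Cal4", NA)[pick + 1]
        }
        rows[[id]] <- data.frame(
          id = id, x0 = (cell - 0.5) * 1000, y0 = 500,
          release_time = rel, cohort = cohort,
          status = status, status_time = st_time,
          first_entry_time = fe,
          strand_coast = coast, strand_segment = seg,
          strand_s = NA_real_, x_final = NA_real_, y_final = NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  particles <- do.call(rbind, rows)

  # Scripted hourly positions: strait region is x in [10000, 12000],
  # y in [0, 3000]. Particle 1 spends hours 0-11 of day 1 inside and the
  # rest of day 1 outside; particle 2 is inside for all 24 h of day 2;
  # particle 3 never enters.
  pos <- rbind(
    data.frame(id = 1, time = (0:11) * 3600, x = 11000, y = 1500),
    data.frame(id = 1, time = (12:23) * 3600, x = 20000, y = 1500),
    data.frame(id = 2, time = 86400 + (0:23) * 3600, x = 10500, y = 2000),
    data.frame(id = 3, time = (0:23) * 3600, x = 40000, y = 9000)
  )
  structure(list(particles = particles, positions = pos,
                 duration = 10 * 86400, seed = NA, record = "all",
                 output_interval = 3600),
            class = "trajectory_set")
}

toy_strait_polygon <- function() {
  rbind(c(10000, 0), c(12000, 0), c(12000, 3000), c(10000, 3000))
}

toy_source_region <- function() {
  rbind(c(0, 0), c(5000, 0), c(5000, 1000), c(0, 1000))
}
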