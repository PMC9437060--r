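# Brute-force recounts of every metric on the hand-built 50-particle
# fixture, plus the forced small examples.

brute_nsi <- function(particles, cells = 1:5, cohorts = 1:2, bin = 1000) {
  ratios <- sapply(cells, function(cell) {
    per_cohort <- sapply(cohorts, function(co) {
      sel <- particles$cohort == co &
        floor(particles$x0 / bin) + 1 == cell
      if (!any(sel)) return(NA_real_)
      sum(!is.na(particles$first_entry_time[sel])) / sum(sel)
    })
    mean(per_cohort, na.rm = TRUE)
  })
  ratios / max(ratios, na.rm = TRUE)
}

test_that("NSI matches a brute-force cohort recount exactly", {
  ts <- toy_trajectory_set()
  grid <- compute_nsi(ts, bin_size = 1000, region = toy_source_region())
  expect_equal(nrow(grid), 5)
  expect_true(attr(grid, "normalization_defined"))
  expect_equal(grid$nsi, brute_nsi(ts$particles))
  expect_equal(max(grid$nsi, na.rm = TRUE), 1)
  # cohort means before normalization: (0.8, 0.6, 0, 1, 0.1)
  expect_equal(grid$ratio, c(0.8, 0.6, 0, 1, 0.1))
})

test_that("NSI normalization and undefined cells follow the definition", {
  # forced: ratios (1, .5, 0) normalize to themselves
  mk <- function(entered, released, cohort = 1) {
    n <- sum(released)
    cell <- rep(seq_along(released), released)
    ent <- unlist(mapply(function(e, r) c(rep(TRUE, e), rep(FALSE, r - e)),
                         entered, released, SIMPLIFY = FALSE))
    structure(list(particles = data.frame(
      id = seq_len(n), x0 = (cell - 0.5) * 1000, y0 = 500,
      release_time = 0, cohort = cohort,
      status = "active", status_time = NA_real_,
      first_entry_time = ifelse(ent, 86400, NA_real_),
      strand_coast = NA_character_, strand_segment = NA_character_,
      strand_s = NA_real_, x_final = NA_real_, y_final = NA_real_),
      positions = data.frame(), duration = 5 * 86400, output_interval = 3600),
      class = "trajectory_set")
  }
  region3 <- rbind(c(0, 0), c(3000, 0), c(3000, 1000), c(0, 1000))
  g <- compute_nsi(mk(c(10, 5, 0), c(10, 10, 10)), 1000, region3)
  expect_equal(g$nsi, c(1, 0.5, 0))
  # all identical ratios -> all NSI 1
  g2 <- compute_nsi(mk(c(4, 4, 4), c(10, 10, 10)), 1000, region3)
  expect_equal(g2$nsi, c(1, 1, 1))
  # two cohorts 0.2 / 0.6 in cell 1, constant 0.8 in cell 2
  ts2 <- mk(c(2, 8), c(10, 10), cohort = 1)
  extra <- mk(c(6, 8), c(10, 10), cohort = 2)
  extra$particles$id <- extra$particles$id + 20
  ts2$particles <- rbind(ts2$particles, extra$particles)
  region2 <- rbind(c(0, 0), c(2000, 0), c(2000, 1000), c(0, 1000))
  g3 <- compute_nsi(ts2, 1000, region2)
  expect_equal(g3$ratio, c(0.4, 0.8))
  expect_equal(g3$nsi, c(0.5, 1))
  # no entrant anywhere -> NSI undefined with explicit flag
  g4 <- compute_nsi(mk(c(0, 0, 0), c(5, 5, 5)), 1000, region3)
  expect_false(attr(g4, "normalization_defined"))
  expect_true(all(is.na(g4$nsi)))
  # cells with no releases are undefined, not zero
  g5 <- compute_nsi(mk(c(3, 0, 2), c(5, 0, 5)), 1000, region3)
  expect_true(is.na(g5$nsi[2]))
  expect_equal(g5$released[2], 0)
})

test_that("travel-time map averages entry ages above the NSI threshold", {
  ts <- toy_trajectory_set()
  grid <- compute_nsi(ts, bin_size = 1000, region = toy_source_region())
  tt <- travel_time_map(ts, grid, nsi_threshold = 0.6)
  # defined exactly for cells with NSI > 0.6 (cells 1 and 4)
  expect_equal(which(!is.na(tt$travel_time)), c(1, 4))
  # brute-force mean age of entrants per cell
  p <- ts$particles
  for (cell in c(1, 4)) {
    sel <- floor(p$x0 / 1000) + 1 == cell & !is.na(p$first_entry_time)
    expect_equal(tt$travel_time[cell],
                 mean(p$first_entry_time[sel] - p$release_time[sel]))
  }
  # two entrants at ages 10 and 30 days -> 20 days
  small <- ts
  small$particles <- data.frame(
    id = 1:2, x0 = 500, y0 = 500, release_time = 0, cohort = 1,
    status = "active", status_time = NA_real_,
    first_entry_time = c(10, 30) * 86400,
    strand_coast = NA_character_, strand_segment = NA_character_,
    strand_s = NA_real_, x_final = NA_real_, y_final = NA_real_)
  g1 <- compute_nsi(small, 1000,
                    rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)))
  t1 <- travel_time_map(small, g1)
  expect_equal(t1$travel_time, 20 * 86400)
})

test_that("entry ratio matches a brute-force daily recount", {
  ts <- toy_trajectory_set()
  er <- entry_ratio_series(ts)
  p <- ts$particles
  for (d in c(1, 2, 3, 5, 8, 10)) {
    t_end <- d * 86400
    ent <- sum(!is.na(p$first_entry_time) & p$first_entry_time < t_end)
    rel <- sum(p$release_time < t_end)
    left <- sum(p$status == "left_domain" & p$status_time < t_end)
    want <- if (rel - left > 0) ent / (rel - left) else NA_real_
    expect_equal(er$ratio[er$day == d], want)
  }
  # nobody enters -> all zeros
  none <- ts
  none$particles$first_entry_time <- NA_real_
  none$particles$status[none$particles$status %in%
    c("exited_tyrrhenian", "exited_ionian")] <- "active"
  expect_true(all(entry_ratio_series(none)$ratio == 0))
})

test_that("entry ratio steps as forced by a single-release scenario", {
  p <- data.frame(
    id = 1:10, x0 = 500, y0 = 500, release_time = 0, cohort = 1,
    status = "active", status_time = NA_real_,
    first_entry_time = 4 * 86400 + 3600,  # during day 5
    strand_coast = NA_character_, strand_segment = NA_character_,
    strand_s = NA_real_, x_final = NA_real_, y_final = NA_real_)
  ts <- structure(list(particles = p, positions = data.frame(),
                       duration = 7 * 86400, output_interval = 3600),
                  class = "trajectory_set")
  er <- entry_ratio_series(ts)
  expect_equal(er$ratio, c(0, 0, 0, 0, 1, 1, 1))
})

test_that("occupancy counts hourly snapshots inside the strait", {
  ts <- toy_trajectory_set()
  occ <- occupancy_series(ts, domain = list(strait_region = toy_strait_polygon()))
  # brute force over the scripted positions
  pos <- ts$positions
  inside <- pos$x >= 10000 & pos$x <= 12000 & pos$y >= 0 & pos$y <= 3000
  for (d in 1:3) {
    sel <- inside & floor(pos$time / 86400) + 1 == d
    expect_equal(occ$count[occ$day == d], sum(sel) / 24)
  }
  expect_equal(occ$count[occ$day == 1], 0.5)  # 12 of 24 snapshots
  expect_equal(occ$count[occ$day == 2], 1)
  expect_true(all(occ$count[occ$day > 2] == 0))
})

test_that("retention ratio matches a brute-force recount", {
  ts <- toy_trajectory_set()
  rr <- retention_ratio_series(ts)
  p <- ts$particles
  for (d in c(2, 4, 6, 10)) {
    t_end <- d * 86400
    ent <- sum(!is.na(p$first_entry_time) & p$first_entry_time < t_end)
    ex <- sum(p$status == "exited_tyrrhenian" & p$status_time < t_end)
    want <- if (ent > 0) ex / ent else NA_real_
    expect_equal(rr$ratio[rr$day == d], want)
  }
  # forced: 10 enter, 4 exit north, 3 exit south -> 0.4 at the end
  p2 <- data.frame(
    id = 1:10, x0 = 500, y0 = 500, release_time = 0, cohort = 1,
    status = c(rep("exited_tyrrhenian", 4), rep("exited_ionian", 3),
               rep("active", 3)),
    status_time = c(rep(2 * 86400, 7), rep(NA_real_, 3)),
    first_entry_time = 3600,
    strand_coast = NA_character_, strand_segment = NA_character_,
    strand_s = NA_real_, x_final = NA_real_, y_final = NA_real_)
  ts2 <- structure(list(particles = p2, positions = data.frame(),
                        duration = 4 * 86400, output_interval = 3600),
                   class = "trajectory_set")
  rr2 <- retention_ratio_series(ts2)
  expect_equal(rr2$ratio[4], 0.4)
})

test_that("stranding shares and the coast ratio match direct counts", {
  ts <- toy_trajectory_set()
  sh <- stranding_shares(ts, segments = toy_segments())
  p <- ts$particles
  ev <- p[p$status == "stranded", ]
  mainland <- ev[ev$strand_coast %in% c("sicily", "calabria"), ]
  expect_equal(sh$total_mainland, nrow(mainland))
  expect_equal(sh$island_count, sum(startsWith(ev$strand_coast, "island")))
  expect_equal(sum(sh$shares$share_pct), 100, tolerance = 1e-9)
  for (seg in c("Sic1", "Cal2", "Cal4")) {
    expect_equal(sh$shares$count[sh$shares$segment_id == seg],
                 sum(mainland$strand_segment == seg))
  }
  expect_equal(sh$coast_ratio,
               sum(mainland$strand_coast == "calabria") /
                 sum(mainland$strand_coast == "sicily"))
})

test_that("stranding share edge cases behave as specified", {
  segs <- toy_segments()
  mk_events <- function(coast, segment) {
    data.frame(strand_coast = coast, strand_segment = segment,
               stringsAsFactors = FALSE)
  }
  # all strandings in one segment
  one <- stranding_shares(mk_events(rep("sicily", 7), rep("Sic2", 7)), segs)
  expect_equal(one$shares$share_pct[one$shares$segment_id == "Sic2"], 100)
  expect_equal(sum(one$shares$share_pct), 100)
  expect_true(is.na(one$coast_ratio) || one$coast_ratio == 0)
  # equal counts on both coasts -> ratio 1
  eq <- stranding_shares(mk_events(c(rep("calabria", 5), rep("sicily", 5)),
                                   c(rep("Cal1", 5), rep("Sic1", 5))), segs)
  expect_equal(eq$coast_ratio, 1)
  # 53 vs 47 -> shares 53%/47%, ratio ~1.13
  counts <- mk_events(c(rep("calabria", 53), rep("sicily", 47)),
                      c(rep("Cal3", 53), rep("Sic3", 47)))
  sh <- stranding_shares(counts, segs)
  tot <- tapply(sh$shares$share_pct, sh$shares$coast, sum)
  expect_equal(unname(tot[["calabria"]]), 53)
  expect_equal(unname(tot[["sicily"]]), 47)
  expect_equal(sh$coast_ratio, 53 / 47)
  # no strandings: zero shares, undefined ratio
  empty <- stranding_shares(mk_events(character(0), character(0)), segs)
  expect_true(all(empty$shares$share_pct == 0))
  expect_true(is.na(empty$coast_ratio))
})
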