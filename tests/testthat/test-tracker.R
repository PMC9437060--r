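test_that("configuration contracts are enforced", {
  expect_error(tracker_config(dt = 0), "dt")
  expect_error(tracker_config(windage_alpha = 2), "windage")
  expect_error(tracker_config(diffusivity = -1), "diffusivity")
  expect_error(tracker_config(dt = 700), "multiple")
  expect_error(release_schedule(toy_source_region(), 10, 5), "precede")
})

test_that("uniform-flow displacement is exact with zero diffusion", {
  fld <- uniform_field(0.5, 0, t_end = 1e5)
  cfg <- tracker_config(dt = 600, output_interval = 600, diffusivity = 0)
  p1 <- step_particles(c(10000, 40000), 0, fld, config = cfg)
  expect_equal(as.numeric(p1), c(10300, 40000))
})

test_that("windage is the configured fraction of wind speed and linear", {
  still <- uniform_field(0, 0, t_end = 1e5)
  wind10 <- wind_series(0, u = 10, v = 0)
  cfg <- tracker_config(dt = 1000, output_interval = 1000, diffusivity = 0)
  p <- step_particles(c(10000, 40000), 0, still, wind = wind10, config = cfg)
  expect_equal(as.numeric(p), c(10040, 40000))  # 0.004 * 10 * 1000
  wind20 <- wind_series(0, u = 20, v = 0)
  p2 <- step_particles(c(10000, 40000), 0, still, wind = wind20, config = cfg)
  expect_equal(p2[1] - 10000, 2 * (p[1] - 10000))
})

test_that("RK4 closes a solid-rotation orbit to within 1e-3 of the radius", {
  period <- 43200
  omega <- 2 * pi / period
  grid <- list(x = seq(100, 19900, 200), y = seq(100, 19900, 200))
  rot <- make_analytic_field("solid_rotation",
                             list(centre = c(10000, 10000), omega = omega),
                             grid, t_end = 2 * period)
  cfg <- tracker_config(dt = 300, output_interval = 300, diffusivity = 0)
  radius <- 1000
  pos <- matrix(c(10000 + radius, 10000), ncol = 2)
  start <- pos
  for (k in seq_len(period / 300)) {
    pos <- step_particles(pos, (k - 1) * 300, rot, config = cfg)
  }
  expect_lt(sqrt(sum((pos - start)^2)), 1e-3 * radius)
})

test_that("pure diffusion reproduces the 4Kt mean squared displacement", {
  K <- 5
  t_final <- 1e4
  dt <- 250
  still <- uniform_field(0, 0, t_end = 2 * t_final)
  cfg <- tracker_config(dt = dt, output_interval = 1000, diffusivity = K)
  n <- 5000
  set.seed(42)
  pos <- cbind(rep(30000, n), rep(40000, n))
  start <- pos
  for (k in seq_len(t_final / dt)) {
    pos <- step_particles(pos, (k - 1) * dt, still, config = cfg)
  }
  msd <- mean(rowSums((pos - start)^2))
  expect_lt(abs(msd - 4 * K * t_final) / (4 * K * t_final), 0.05)
})

test_that("halving the time step barely moves double-gyre endpoints", {
  grid <- list(x = seq(100, 19900, 200), y = seq(100, 9900, 200))
  gyre <- make_analytic_field("double_gyre", list(psi0 = 2000), grid,
                              t_end = 1e5)
  run <- function(dt) {
    cfg <- tracker_config(dt = dt, output_interval = dt, diffusivity = 0)
    pos <- rbind(c(4000, 3000), c(12000, 7000), c(9000, 5000))
    for (k in seq_len(43200 / dt)) {
      pos <- step_particles(pos, (k - 1) * dt, gyre, config = cfg)
    }
    pos
  }
  coarse <- run(600)
  fine <- run(300)
  # path length ~ speed * time; typical speed O(0.5 m/s)
  v <- eval_velocity(gyre, c(4000, 12000, 9000), c(3000, 7000, 5000), 0)
  path_len <- sqrt(v$u^2 + v$v^2) * 43200
  expect_true(all(sqrt(rowSums((coarse - fine)^2)) < 0.01 * path_len))
})

test_that("stepping outside the field's time coverage errors", {
  fld <- uniform_field(0.1, 0, t_end = 1000)
  cfg <- tracker_config(dt = 600, output_interval = 600, diffusivity = 0)
  expect_error(step_particles(c(1000, 1000), 900, fld, config = cfg),
               "coverage")
})

test_that("uniform seeding is reproducible, in-water and uniform", {
  dom <- fixture_domain()
  rect <- rbind(c(34000, 40000), c(54000, 40000), c(54000, 60000),
                c(34000, 60000))
  set.seed(3)
  a <- seed_uniform(dom, rect, 4)
  set.seed(3)
  b <- seed_uniform(dom, rect, 4)
  expect_identical(a, b)
  expect_true(all(points_in_polygon(a[, 1], a[, 2], rect)))

  set.seed(5)
  big <- seed_uniform(dom, rect, 10000)
  # mean within 3 sigma of the rectangle centre
  se <- 20000 / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(big[, 1]) - 44000), 3 * se)
  expect_lt(abs(mean(big[, 2]) - 50000), 3 * se)
  # chi-square uniformity over a 4x4 partition
  ix <- findInterval(big[, 1], seq(34000, 54000, length.out = 5),
                     all.inside = TRUE)
  iy <- findInterval(big[, 2], seq(40000, 60000, length.out = 5),
                     all.inside = TRUE)
  expect_gt(stats::chisq.test(table(ix, iy))$p.value, 0.01)

  # a region straddling the coast seeds only its water half
  straddle <- rbind(c(40000, 30000), c(50000, 30000), c(50000, 40000),
                    c(40000, 40000))
  set.seed(6)
  w <- seed_uniform(dom, straddle, 500)
  expect_true(all(w[, 2] > 35000))

  land_only <- rbind(c(5000, 5000), c(10000, 5000), c(10000, 10000),
                     c(5000, 10000))
  expect_error(seed_uniform(dom, land_only, 10), "no water")
})

test_that("null dynamics leave all particles active and unmoved", {
  dom <- fixture_domain()
  fld <- uniform_field(0, 0, t_end = 3 * 86400)
  sched <- release_schedule(dom$spawning_region, 0, 3600,
                            release_interval = 86400,
                            particles_per_release = 100)
  ts <- run_experiment(fld, NULL, dom, sched,
                       tracker_config(diffusivity = 0), 2 * 86400, seed = 8)
  p <- ts$particles
  expect_equal(nrow(p), 100)
  expect_true(all(p$status == "active"))
  expect_equal(p$x_final, p$x0)
  expect_equal(p$y_final, p$y0)
})

test_that("compiled and reference steppers agree on uniform flow", {
  dom <- fixture_domain()
  fld <- uniform_field(0.05, 0, t_end = 2 * 86400)
  rect <- rbind(c(36000, 50000), c(40000, 50000), c(40000, 54000),
                c(36000, 54000))
  sched <- release_schedule(rect, 0, 3600, release_interval = 86400,
                            particles_per_release = 20)
  ts <- run_experiment(fld, NULL, dom, sched,
                       tracker_config(diffusivity = 0), 86400, seed = 8)
  p <- ts$particles
  expect_true(all(p$status == "active"))
  expect_equal(p$x_final, p$x0 + 0.05 * 86400, tolerance = 1e-10)
})

test_that("flow toward a coast strands everyone in distance order", {
  dom <- fixture_domain()
  fld <- uniform_field(0.3, 0, t_end = 5 * 86400)
  sched <- release_schedule(dom$strait_region, 0, 3600,
                            release_interval = 86400,
                            particles_per_release = 200)
  ts <- run_experiment(fld, NULL, dom, sched,
                       tracker_config(diffusivity = 0), 2 * 86400, seed = 9)
  p <- ts$particles
  expect_true(all(p$status == "stranded"))
  expect_true(all(p$strand_coast == "calabria"))
  dist <- 33000 - p$x0
  st <- p$status_time[order(dist)]
  expect_true(all(diff(st) >= -1e-6))
  # stranding time matches distance / speed
  expect_equal(p$status_time, (33000 - p$x0) / 0.3, tolerance = 1e-3)
})

test_that("release bookkeeping accounts for every particle", {
  dom <- fixture_domain()
  fld <- uniform_field(0, 0, t_end = 11 * 44712 + 86400)
  sched <- release_schedule(dom$spawning_region, 0, 9.5 * 44712,
                            release_interval = 44712,
                            particles_per_release = 50)
  ts <- run_experiment(fld, NULL, dom, sched,
                       tracker_config(diffusivity = 0), 6 * 86400, seed = 1,
                       record = "none")
  expect_equal(nrow(ts$particles), 10 * 50)
  cons <- conservation_table(ts)
  expect_true(all(cons$released == cons$active + cons$stranded +
                    cons$exited_tyrrhenian + cons$exited_ionian +
                    cons$left_domain))
})

test_that("runs are reproducible for a fixed seed", {
  dom <- fixture_domain()
  fld <- fixture_strait_field(4 * 86400)
  wind <- make_wind_series(flow_config(), 4 * 86400, seed = 21)
  sched <- release_schedule(dom$strait_region, 0, 86400,
                            particles_per_release = 30)
  cfg <- tracker_config()
  a <- run_experiment(fld, wind, dom, sched, cfg, 3 * 86400, seed = 4)
  b <- run_experiment(fld, wind, dom, sched, cfg, 3 * 86400, seed = 4)
  expect_identical(a$particles, b$particles)
  expect_identical(a$positions, b$positions)
})
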