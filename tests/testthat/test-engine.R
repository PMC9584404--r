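make_state <- function(lon, lat, depth, age = 0, fate = "alive") {
  n <- max(length(lon), length(lat), length(depth), length(age))
  data.frame(id = seq_len(n), lon = rep_len(lon, n), lat = rep_len(lat, n),
             depth = rep_len(depth, n), age = rep_len(age, n),
             fate = rep_len(fate, n), settled_island = NA_character_,
             temp = NA_real_, salt = NA_real_, settle_time = NA_real_,
             settle_dps = NA_real_)
}

test_that("CFL timestep bound follows 0.7 * dGrid / Umax", {
  expect_equal(cfl_max_dt(3100, 1), 2170)
  expect_equal(cfl_max_dt(3100, 0.2), 10850)
  expect_equal(cfl_max_dt(3100, 0.4), cfl_max_dt(3100, 0.2) / 2)
  expect_error(cfl_max_dt(-1, 1))
  # the engine refuses configurations beyond the bound
  expect_error(engine_config(dt = 10800, dgrid = 3100, umax = 1),
               "CFL")
})

test_that("Okubo diffusivity matches the cgs power law", {
  # hand evaluation: 0.0103 * (l_cm)^1.15 cm^2/s -> m^2/s
  expect_equal(okubo_kh(3100), 0.0103 * (3.1e5)^1.15 * 1e-4,
               tolerance = 1e-12)
  expect_equal(okubo_kh(3100), 2.13, tolerance = 0.01)
  expect_equal(okubo_kh(1000), 0.58, tolerance = 0.01)
  expect_equal(okubo_kh(2000) / okubo_kh(1000), 2^1.15, tolerance = 1e-12)
  expect_error(okubo_kh(0))
})

test_that("uniform-field Euler advection is exact after unit conversion", {
  f <- make_test_field(current = list(speed = 0.1, bearing = 90), days = 2)
  s <- make_state(-77.5, 26, 50)
  s2 <- advect_euler(s, f, 0, 10800)
  expect_equal((s2$lon - s$lon) * 111320 * cos(s$lat * pi / 180),
               0.1 * 10800, tolerance = 1e-7)
  expect_equal(s2$lat, s$lat)
  expect_equal(s2$depth, s$depth)

  # zero field: identity
  f0 <- make_test_field(days = 2)
  s3 <- advect_euler(s, f0, 0, 10800)
  expect_equal(s3$lon, s$lon)
  expect_equal(s3$lat, s$lat)
})

test_that("Euler in a solid-body gyre drifts outward within the bound and converges at first order", {
  gy <- list(lon = -77.5, lat = 0.5, radius = 30000, vmax = 0.3,
             sense = 1, profile = "solid")
  f <- make_test_field(gyre = gy, lon = seq(-78, -77, 0.02),
                       lat = seq(0, 1, 0.02), days = 30)
  omega <- gy$vmax / gy$radius
  r0 <- 5000
  m_per_lon <- 111320 * cos(gy$lat * pi / 180)
  start <- make_state(gy$lon + r0 / m_per_lon, gy$lat, 50)

  # single step: outward radial drift <= (1/2) omega^2 r dt^2
  dt <- 10800
  s1 <- advect_euler(start, f, 0, dt)
  r1 <- sqrt(((s1$lon - gy$lon) * m_per_lon)^2 +
               ((s1$lat - gy$lat) * 111320)^2)
  expect_gt(r1, r0)
  expect_lt(r1 - r0, 0.5 * omega^2 * r0 * dt^2 * 1.01)

  # error vs the analytic rotation halves with the step size
  advance <- function(dt, total) {
    s <- start
    for (k in seq_len(round(total / dt))) {
      s <- advect_euler(s, f, (k - 1) * dt, dt)
    }
    c(x = (s$lon - gy$lon) * m_per_lon, y = (s$lat - gy$lat) * 111320)
  }
  total <- 20 * 10800
  exact <- rotate_exact(r0, 0, omega, total)
  err <- function(dt) sqrt(sum((advance(dt, total) - exact)^2))
  ratio <- err(10800) / err(5400)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("horizontal dispersion has bounded support and diffusive variance", {
  expect_equal(horizontal_dispersion_step(0, 10800, 5),
               cbind(dx = rep(0, 5), dy = rep(0, 5)))
  expect_error(horizontal_dispersion_step(-1, 10800))

  kh <- 2.13; dt <- 10800
  set.seed(99)
  d <- horizontal_dispersion_step(kh, dt, 1e5)
  amp <- sqrt(6 * kh * dt)
  expect_true(all(abs(d) <= amp))
  # mean squared planar displacement ~ 4 kh dt
  expect_equal(mean(d[, 1]^2 + d[, 2]^2), 4 * kh * dt, tolerance = 0.02)
})

test_that("vertical dispersion reflects at the boundaries and mixes uniformly", {
  expect_equal(reflect_depth(-1, 100), 1)
  expect_equal(reflect_depth(150, 100), 50)
  expect_equal(reflect_depth(c(0, 50, 100), 100), c(0, 50, 100))

  # kz = 0: no vertical motion
  expect_equal(vertical_dispersion_step(c(10, 20), c(0, 0), 10800, 100),
               c(10, 20))

  # well-mixed condition: constant kz in a reflecting column leaves a
  # long-run depth distribution uniform (independent particles)
  set.seed(7)
  H <- 50; kz <- 1e-3; dt <- 600
  z <- rep(H / 2, 2000)
  for (s in seq_len(2500)) z <- vertical_dispersion_step(z, rep(kz, 2000),
                                                         dt, H)
  ks <- suppressWarnings(ks.test(z, "punif", 0, H))
  expect_gt(ks$p.value, 0.01)
})

test_that("step fates: domain exit and pre-competency beaching are absorbing", {
  # westward current from near the western edge exits the domain
  f <- make_test_field(current = list(speed = 0.5, bearing = 270), days = 2)
  cfg <- engine_config(dt = 10800, dgrid = 10000, umax = 0.6, kh = 0,
                       n_iterations = 1, duration = 2)
  sch <- density_schedule()
  s <- make_state(-77.97, 26, 50)
  s <- step_particles(s, f, NULL, bio_rules(), cfg, sch, 0)
  expect_equal(s$fate, "out_of_domain")
  frozen <- step_particles(s, f, NULL, bio_rules(), cfg, sch, 10800)
  expect_identical(frozen, s)

  # a young particle carried onto a land cell beaches
  fi <- make_test_field(current = list(speed = 0.5, bearing = 90),
                        coast = list(type = "halfplane", side = "E",
                                     position = -76.5), days = 2)
  s2 <- make_state(-76.56, 26, 50, age = 10)
  s2 <- step_particles(s2, fi, NULL, bio_rules(), cfg, sch, 0)
  expect_equal(s2$fate, "dead_beached")
})

test_that("replicated runs conserve counts, keep cadence and reproduce bitwise", {
  fix <- make_small_run(n_particles = 20, n_iterations = 2, days = 10)
  run <- fix$run
  # 10 days at 3 h cadence: 81 records
  expect_equal(nrow(run$iterations[[1]]$traj$lon), 10 * 8 + 1)

  # conservation at every record: fates partition the release
  f <- run$iterations[[1]]$traj$fate
  counts <- t(apply(f, 1, function(r) tabulate(r + 1L, 6L)))
  expect_true(all(rowSums(counts) == 20))

  # determinism: identical seeds give identical trajectories
  run2 <- run_simulation(fix$release, fix$field, bio_rules(), fix$zones,
                         fix$config)
  expect_identical(run2$iterations[[1]]$traj, run$iterations[[1]]$traj)
  expect_identical(run2$iterations[[2]]$traj, run$iterations[[2]]$traj)

  # iteration seeds are pure and distinct
  expect_identical(iteration_seed(5, 3), iteration_seed(5, 3))
  expect_false(iteration_seed(5, 3) == iteration_seed(5, 4))

  # a field too short in time is refused
  shortf <- make_test_field(days = 3)
  expect_error(run_simulation(fix$release, shortf, bio_rules(), NULL,
                              fix$config),
               "time span")
})

test_that("pure-advection displacement matches u*t and pure diffusion matches <r^2> = 4 kh t", {
  f <- make_test_field(current = list(speed = 0.05, bearing = 90), days = 6)
  ev <- spawning_event(lon = -77.8, lat = 26, n_particles = 1,
                       stain_radius = 1)
  rel <- release_stain(ev, c(49, 51), seed = 1)
  cfg <- engine_config(dt = 10800, dgrid = 5500, umax = 0.3, kh = 0,
                       n_iterations = 1, duration = 5, buoyancy = FALSE)
  run <- run_simulation(rel, f, bio_rules(), NULL, cfg)
  tr <- run$iterations[[1]]$traj
  n_rec <- nrow(tr$lon)
  dx <- (tr$lon[n_rec, 1] - tr$lon[1, 1]) * 111320 *
    cos(tr$lat[1, 1] * pi / 180)
  expect_equal(dx, 0.05 * 5 * 86400, tolerance = 1e-6)

  # pure diffusion: no advection, larvae spread diffusively
  f0 <- make_test_field(days = 6)
  ev2 <- spawning_event(lon = -77.5, lat = 26, n_particles = 400,
                        stain_radius = 1)
  rel2 <- release_stain(ev2, c(49, 51), seed = 2)
  kh <- 2
  cfg2 <- engine_config(dt = 10800, dgrid = 5500, umax = 0.3, kh = kh,
                        n_iterations = 2, duration = 5, buoyancy = FALSE)
  run2 <- run_simulation(rel2, f0, bio_rules(), NULL, cfg2)
  t_el <- 5 * 86400
  msd <- mean(vapply(run2$iterations, function(it) {
    tr <- it$traj
    n_rec <- nrow(tr$lon)
    dx <- (tr$lon[n_rec, ] - tr$lon[1, ]) * 111320 *
      cos(tr$lat[1, ] * pi / 180)
    dy <- (tr$lat[n_rec, ] - tr$lat[1, ]) * 111320
    mean(dx^2 + dy^2)
  }, numeric(1)))
  expect_equal(msd, 4 * kh * t_el, tolerance = 0.1)
})
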