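# Hand-built ldm_run-shaped objects let the aggregation operations be
# checked against enumerable fixtures without running the engine.
fake_levels <- c(alive = 0L, out_of_domain = 1L, dead_beached = 2L,
                 dead_cold = 3L, dead_hot = 4L, settled = 5L)

fake_run <- function(iterations, islands = character()) {
  structure(list(iterations = iterations, fate_levels = fake_levels,
                 islands = islands), class = "ldm_run")
}

fake_iter <- function(time, lon, lat, depth = NULL, temp = NULL,
                      salt = NULL, fate = NULL, settlement = NULL) {
  n_rec <- length(time); n <- ncol(lon)
  zeros <- matrix(0, n_rec, n)
  list(traj = list(time = time, lon = lon, lat = lat,
                   depth = depth %||% zeros, temp = temp %||% zeros,
                   salt = salt %||% zeros,
                   fate = fate %||% matrix(0L, n_rec, n)),
       settlement = settlement %||%
         data.frame(iteration = integer(), larva = integer(),
                    island = character(), time = numeric(),
                    dps = numeric(), lon = numeric(), lat = numeric()))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# plain haversine, written out for use as an oracle
hav_km <- function(lon1, lat1, lon2, lat2) {
  to_r <- pi / 180
  dphi <- (lat2 - lat1) * to_r; dlam <- (lon2 - lon1) * to_r
  a <- sin(dphi / 2)^2 +
    cos(lat1 * to_r) * cos(lat2 * to_r) * sin(dlam / 2)^2
  2 * 6371 * asin(sqrt(a))
}

test_that("fate proportions average iterations and always sum to one", {
  # 4 particles, 3 daily records; half beach on day 1 and stay beached
  time <- c(0, 1, 2) * 86400
  fate <- rbind(c(0L, 0L, 0L, 0L), c(2L, 2L, 0L, 0L), c(2L, 2L, 0L, 0L))
  pos <- matrix(0, 3, 4)
  run <- fake_run(list(fake_iter(time, pos, pos, fate = fate)))
  fp <- fate_proportions(run)
  beached <- fp[fp$fate == "dead_beached", ]
  expect_equal(beached$proportion[beached$day == 0], 0)
  expect_equal(beached$proportion[beached$day == 1], 0.5)
  expect_equal(beached$proportion[beached$day == 2], 0.5)
  sums <- tapply(fp$proportion, fp$day, sum)
  expect_equal(as.numeric(sums), rep(1, 3))

  # all-alive run: alive proportion 1 every day
  run2 <- fake_run(list(fake_iter(time, pos, pos)))
  fp2 <- fate_proportions(run2)
  expect_true(all(fp2$proportion[fp2$fate == "alive"] == 1))
})

test_that("gridded density matches brute-force binning", {
  lonb <- seq(-78, -77, 0.25); latb <- seq(25, 26, 0.25)
  # one stationary particle over 10 records lands 10 counts in its cell
  time <- (0:9) * 10800
  lon1 <- matrix(-77.6, 10, 1); lat1 <- matrix(25.6, 10, 1)
  run1 <- fake_run(list(fake_iter(time, lon1, lat1)))
  gd1 <- gridded_density(run1, lonb, latb, mode = "all")
  expect_equal(sum(gd1$counts), 10)
  expect_equal(gd1$counts[findInterval(-77.6, lonb),
                          findInterval(25.6, latb)], 10)

  # randomized positions against an independent per-record binning loop
  set.seed(5)
  n_rec <- 6; n <- 25
  lon <- matrix(runif(n_rec * n, -78, -77), n_rec, n)
  lat <- matrix(runif(n_rec * n, 25, 26), n_rec, n)
  fate <- matrix(0L, n_rec, n)
  fate[5:6, 1:5] <- 1L  # these leave the domain: last alive record counts
  run <- fake_run(list(fake_iter(time[1:n_rec], lon, lat, fate = fate)))
  gd <- gridded_density(run, lonb, latb, mode = "all")
  brute <- matrix(0L, length(lonb) - 1, length(latb) - 1)
  for (k in seq_len(n_rec)) {
    for (p in seq_len(n)) {
      counts_this <- fate[k, p] == 0L
      if (counts_this) {
        i <- max(which(lonb <= lon[k, p])); j <- max(which(latb <= lat[k, p]))
        brute[i, j] <- brute[i, j] + 1L
      }
    }
  }
  expect_equal(unname(gd$counts), unname(brute))

  # final-step mode counts only larvae still in-domain at the end
  gdf <- gridded_density(run, lonb, latb, mode = "final")
  expect_equal(sum(gdf$counts), n - 5)
})

test_that("path length and coefficient of dispersal follow haversine geometry", {
  # 1 degree of longitude along the equator
  expect_equal(path_length(c(0, 1), c(0, 0)), 111.19, tolerance = 1e-3)
  # identical consecutive points contribute nothing
  expect_equal(path_length(c(5, 5), c(2, 2)), 0)
  # concatenation additivity
  lon <- c(0, 0.5, 1.2, 2); lat <- c(0, 0.3, 0.1, 0.4)
  expect_equal(path_length(lon, lat),
               path_length(lon[1:3], lat[1:3]) + path_length(lon[3:4],
                                                             lat[3:4]))

  # straight track along the equator: path equals chord
  expect_equal(coefficient_of_dispersal(c(0, 1, 2), c(0, 0, 0)), 1,
               tolerance = 1e-9)

  # planar 3-4-5 right angle at small scale: ratio 5/7
  km_lon <- 1 / hav_km(0, 0, 1, 0)  # degrees per km at the equator
  lon3 <- c(0, 3 * km_lon, 3 * km_lon)
  lat3 <- c(0, 0, 4 * km_lon)
  expect_equal(coefficient_of_dispersal(lon3, lat3), 5 / 7,
               tolerance = 1e-4)

  expect_error(coefficient_of_dispersal(c(1, 1), c(2, 2)), "zero path")
})

test_that("settlement KDE is max-normalized and conserves kernel mass", {
  # a single point produces a peak of exactly 1 at the point
  kde1 <- settlement_kde(-77.5, 26, bandwidth = c(0.1, 0.1))
  expect_equal(max(kde1$z), 1)
  peak <- which(kde1$z == 1, arr.ind = TRUE)
  expect_equal(kde1$x[peak[1]], -77.5, tolerance = 0.01)
  expect_equal(kde1$y[peak[2]], 26, tolerance = 0.01)

  # two distant equal clusters: two modes of equal height ~1
  set.seed(8)
  lon <- c(rnorm(200, -78, 0.02), rnorm(200, -76, 0.02))
  lat <- c(rnorm(200, 25, 0.02), rnorm(200, 26.5, 0.02))
  kde2 <- settlement_kde(lon, lat, bandwidth = c(0.1, 0.1), gridsize = 121)
  west <- kde2$z[kde2$x < -77, ]
  east <- kde2$z[kde2$x > -77, ]
  expect_equal(max(west), 1, tolerance = 0.1)
  expect_equal(max(east), 1, tolerance = 0.1)

  # the raw density integrates to ~1 (mass conservation per point)
  dx <- diff(kde2$x)[1]; dy <- diff(kde2$y)[1]
  expect_equal(sum(kde2$z_raw) * dx * dy, 1, tolerance = 0.05)

  expect_error(settlement_kde(numeric(), numeric()), "at least one")
})

test_that("connectivity matrix and footprints match hand counts", {
  rec <- data.frame(
    iteration = c(1, 1, 2, 2, 2, 3, 3, 1),
    larva = 1:8,
    island = c("A", "B", "A", "A", "C", "B", "B", "A"))
  cm <- connectivity_matrix(rec, 3)
  expect_equal(cm$n_settled[cm$island == "A"], 4L)
  expect_equal(cm$iteration_fraction[cm$island == "A"], 2 / 3)
  expect_equal(cm$iteration_fraction[cm$island == "C"], 1 / 3)
  # totals equal an independent group-by tally
  expect_equal(setNames(cm$n_settled, cm$island),
               vapply(split(rec$island, rec$island), length, integer(1)))
  # islands with settlers have positive iteration fractions
  expect_true(all(cm$iteration_fraction[cm$n_settled > 0] > 0))

  empty <- rec[0, ]
  cm0 <- connectivity_matrix(empty, 3, islands = c("A", "B"))
  expect_equal(cm0$n_settled, c(0L, 0L))
  expect_equal(cm0$iteration_fraction, c(0, 0))
  expect_error(connectivity_matrix(transform(rec, iteration = iteration + 9),
                                   3), "outside")

  fp <- settlement_footprints(rec, 4)
  expect_equal(sum(fp$frequency), 1)
  expect_equal(fp$n_iterations[fp$footprint == "A + B"], 1L)  # iteration 1
  expect_equal(fp$n_iterations[fp$footprint == "A + C"], 1L)  # iteration 2
  expect_equal(fp$n_iterations[fp$footprint == "B"], 1L)      # iteration 3
  expect_equal(fp$n_iterations[fp$footprint == "(none)"], 1L) # iteration 4

  all_a <- data.frame(iteration = 1:5, larva = 1:5, island = "A")
  fpa <- settlement_footprints(all_a, 5)
  expect_equal(fpa$footprint, "A")
  expect_equal(fpa$frequency, 1)
  fp0 <- settlement_footprints(empty, 3)
  expect_equal(fp0$footprint, "(none)")
  expect_equal(fp0$frequency, 1)
})

test_that("development-environment summaries cover release to settlement", {
  # two records, temperatures 20 then 30, settling at the second record
  time <- c(0, 45 * 86400)
  lon <- matrix(c(-77.5, -77.0), 2, 1); lat <- matrix(26, 2, 1)
  temp <- matrix(c(20, 30), 2, 1); salt <- matrix(c(36, 36.4), 2, 1)
  depth <- matrix(c(100, 2), 2, 1)
  fate <- matrix(c(0L, 5L), 2, 1)
  sett <- data.frame(iteration = 1L, larva = 1L, island = "A",
                     time = 45 * 86400, dps = 45, lon = -77.0, lat = 26)
  run <- fake_run(list(fake_iter(time, lon, lat, depth, temp, salt, fate,
                                 sett)))
  dev <- dev_env_records(run)
  expect_equal(nrow(dev), 1)
  expect_equal(dev$temp_mean, 25)
  expect_equal(dev$temp_min, 20)
  expect_equal(dev$temp_max, 30)
  expect_equal(dev$release_depth, 100)
  expect_equal(dev$mean_depth, 51)
  expect_equal(dev$coefficient, 1, tolerance = 1e-9)  # straight two points
  expect_true(dev$coefficient > 0 & dev$coefficient <= 1)
})

test_that("dev-env invariants hold on an end-to-end run", {
  fix <- make_small_run(n_particles = 40, n_iterations = 2)
  dev <- dev_env_records(fix$run)
  expect_gt(nrow(dev), 0)
  expect_true(all(dev$coefficient > 0 & dev$coefficient <= 1))
  expect_true(all(dev$temp_min <= dev$temp_mean &
                    dev$temp_mean <= dev$temp_max))
  expect_true(all(dev$salt_min <= dev$salt_mean &
                    dev$salt_mean <= dev$salt_max))
  expect_true(all(dev$dps >= 41 & dev$dps <= 71))
  # DVM holds competent larvae shallow, so the mean dispersal depth of a
  # settler sits above its release depth
  expect_true(all(dev$mean_depth < dev$release_depth))
})
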