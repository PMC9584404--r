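# Lagrangian engine: CFL-checked Forward Euler advection, uniform-increment
# random-walk dispersion, biology application, fate bookkeeping, and
# replicated simulation with 3-hourly trajectory recording.

FATE_LEVELS <- c(alive = 0L, out_of_domain = 1L, dead_beached = 2L,
                 dead_cold = 3L, dead_hot = 4L, settled = 5L)

#' Maximum stable timestep under the fine-scale CFL criterion
#'
#' `dt_max = 0.7 * dGrid / Umax`, where `dGrid` is the average grid-cell
#' length and `Umax` the order of magnitude of the fastest currents.
#'
#' @param dgrid Grid spacing, m.
#' @param umax Fastest current speed scale, m/s.
#' @return Maximum timestep, s.
#' @export
cfl_max_dt <- function(dgrid, umax) {
  stopifnot(dgrid > 0, umax > 0)
  0.7 * dgrid / umax
}

#' Okubo horizontal diffusivity for a length scale
#'
#' Okubo's empirical ocean-diffusion power law, `K_h = 0.0103 * l^1.15` in
#' cgs units (l in cm, K_h in cm^2/s), evaluated at the grid length scale
#' and returned in m^2/s. For a 3.1 km grid this gives about 2.1 m^2/s.
#'
#' @param length_scale Length scale, m (e.g. the grid spacing).
#' @return Horizontal diffusivity, m^2/s.
#' @export
okubo_kh <- function(length_scale) {
  stopifnot(length_scale > 0)
  0.0103 * (length_scale * 100)^1.15 * 1e-4
}

#' Engine configuration
#'
#' @param dt Computational timestep, s (default 10800 = 3 h, the cadence of
#'   the forcing fields).
#' @param dgrid Grid spacing, m (default 3100).
#' @param umax Order of magnitude of the fastest currents, m/s. `dt` must
#'   not exceed the CFL bound `0.7 * dgrid / umax`.
#' @param kh Horizontal diffusivity, m^2/s; default scales Okubo's law to
#'   `dgrid`.
#' @param n_iterations Replicate simulations (default 100).
#' @param seed Master seed; per-iteration seeds are a pure function of
#'   (seed, iteration).
#' @param record_interval Trajectory recording cadence, s; `dt` must divide
#'   it.
#' @param duration Simulated duration, days (default 71, the pelagic larval
#'   duration).
#' @param buoyancy Apply the Stokes buoyancy velocity in the depth update?
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(dt = 10800, dgrid = 3100, umax = 0.2,
                          kh = NULL, n_iterations = 100, seed = 1L,
                          record_interval = 10800, duration = 71,
                          buoyancy = TRUE) {
  kh <- kh %||% okubo_kh(dgrid)
  stopifnot(dt > 0, duration > 0, n_iterations > 0, kh >= 0)
  bound <- cfl_max_dt(dgrid, umax)
  if (dt > bound + 1e-9) {
    stop("dt = ", dt, " s exceeds the CFL bound 0.7*dGrid/Umax = ",
         round(bound, 1), " s for dGrid = ", dgrid, " m, Umax = ", umax,
         " m/s")
  }
  if (abs(record_interval / dt - round(record_interval / dt)) > 1e-9) {
    stop("dt must divide record_interval")
  }
  structure(list(dt = dt, dgrid = dgrid, umax = umax, kh = kh,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 record_interval = record_interval, duration = duration,
                 buoyancy = isTRUE(buoyancy)),
            class = "engine_config")
}

#' Per-iteration seed derivation
#'
#' A pure, order-independent function of the master seed and the iteration
#' index (counter-based linear-congruential mix, kept within 32-bit range).
#'
#' @param master Master seed (integer).
#' @param iteration Iteration index (1-based).
#' @return An integer seed.
#' @export
iteration_seed <- function(master, iteration) {
  as.integer((as.numeric(master) %% 2147483647 * 69069 + 1013904223 +
                as.numeric(iteration) * 104729) %% 2147483647)
}

#' Forward Euler advection step
#'
#' Displaces positions by the locally interpolated velocity times `dt`:
#' tri-linear interpolation in (lon, lat, depth), linear in time, with
#' metres-to-degrees conversion at the particle latitude (111320 m per
#' degree latitude, scaled by cos(lat) for longitude). `w` is positive down.
#'
#' @param state Data.frame with `lon`, `lat`, `depth` columns (degrees, m).
#' @param field An [ocean_field()].
#' @param t Current time, s (must lie in the field's time span).
#' @param dt Timestep, s.
#' @return `state` with displaced positions.
#' @export
advect_euler <- function(state, field, t, dt) {
  uvw <- sample_field(field, c("u", "v", "w"),
                      state$lon, state$lat, state$depth, t)
  state$lon <- state$lon +
    uvw[, "u"] * dt / (M_PER_DEG * cos(state$lat * pi / 180))
  state$lat <- state$lat + uvw[, "v"] * dt / M_PER_DEG
  state$depth <- pmax(state$depth + uvw[, "w"] * dt, 0)
  state
}

#' Horizontal random-walk displacement
#'
#' Per-axis displacement `delta * sqrt(6 * kh * dt)` with `delta ~ U[-1, 1]`
#' drawn independently per axis; since `Var(delta) = 1/3` each component's
#' variance is `2 * kh * dt`, so the ensemble mean squared planar
#' displacement is `4 * kh * dt` — the 2-D diffusive scaling.
#'
#' @param kh Horizontal diffusivity, m^2/s.
#' @param dt Timestep, s.
#' @param n Number of particles.
#' @return An `n x 2` matrix of (dx, dy) in metres.
#' @export
horizontal_dispersion_step <- function(kh, dt, n = 1) {
  if (kh < 0) stop("kh must be non-negative")
  amp <- sqrt(6 * kh * dt)
  cbind(dx = runif(n, -1, 1) * amp, dy = runif(n, -1, 1) * amp)
}

#' Reflect depths into a water column
#'
#' Mirrors proposed depths at the surface (0) and the local bottom until
#' they fall inside `[0, bottom]`.
#'
#' @param depth Proposed depth vector, m (may be outside the column).
#' @param bottom Column bottom depth, m.
#' @return Reflected depth vector in `[0, bottom]`.
#' @export
reflect_depth <- function(depth, bottom) {
  stopifnot(bottom > 0)
  d <- depth %% (2 * bottom)
  d <- ifelse(d < 0, d + 2 * bottom, d)
  ifelse(d > bottom, 2 * bottom - d, d)
}

#' Vertical random-walk step with reflecting boundaries
#'
#' Depth increment `delta * sqrt(6 * kz * dt)` with `delta ~ U[-1, 1]` and
#' `kz` the vertical diffusivity interpolated at the particle, reflected at
#' the surface and the local bottom. With constant `kz` this satisfies the
#' well-mixed condition (a uniform depth distribution stays uniform).
#'
#' @param depth Current depth vector, m.
#' @param kz Local vertical diffusivity vector, m^2/s.
#' @param dt Timestep, s.
#' @param bottom Column bottom depth, m.
#' @return New depth vector.
#' @export
vertical_dispersion_step <- function(depth, kz, dt, bottom) {
  kz <- pmax(kz, 0, na.rm = TRUE)
  amp <- sqrt(6 * kz * dt)
  reflect_depth(depth + runif(length(depth), -1, 1) * amp, bottom)
}

#' @noRd
new_particle_state <- function(release) {
  n <- length(release$lon)
  data.frame(id = seq_len(n), lon = release$lon, lat = release$lat,
             depth = release$depth, age = 0, fate = "alive",
             settled_island = NA_character_,
             temp = NA_real_, salt = NA_real_,
             settle_time = NA_real_, settle_dps = NA_real_)
}

#' One engine timestep over a particle ensemble
#'
#' Applies the fixed update order to all alive particles: Forward Euler
#' advection; horizontal and vertical random-walk dispersion; Stokes
#' buoyancy (suppressed while the DVM clamp is active); DVM clamp;
#' temperature/salinity sampling; thermal fate; beaching fate;
#' out-of-domain check; settlement check. Fates are absorbing — rows with a
#' non-alive fate pass through untouched — and each particle receives
#' exactly one fate per step.
#'
#' @param state Particle state data.frame (see [run_simulation()]).
#' @param field An [ocean_field()].
#' @param zones A [load_zones()] result (or `NULL` for no settlement).
#' @param rules A [bio_rules()].
#' @param config An [engine_config()].
#' @param schedule A [density_schedule()] (used when `config$buoyancy`).
#' @param t Time at the start of the step, s.
#' @return Updated state at `t + dt`.
#' @export
step_particles <- function(state, field, zones, rules, config, schedule,
                           t) {
  alive <- state$fate == "alive"
  if (!any(alive)) return(state)
  dt <- config$dt
  s <- state[alive, ]
  bottom <- max(field$depth)

  s <- advect_euler(s, field, t, dt)

  hd <- horizontal_dispersion_step(config$kh, dt, nrow(s))
  s$lon <- s$lon + hd[, "dx"] / (M_PER_DEG * cos(s$lat * pi / 180))
  s$lat <- s$lat + hd[, "dy"] / M_PER_DEG
  kz <- sample_field(field, "kz", s$lon, s$lat, s$depth,
                     min(t + dt, max(field$time)))[, 1]
  s$depth <- vertical_dispersion_step(s$depth, kz, dt, bottom)

  s$age <- s$age + dt / 86400
  clamped <- s$age >= rules$competency[1] & s$age <= rules$competency[2]
  if (config$buoyancy) {
    wb <- stokes_velocity(density_ratio(schedule, s$age, rules$pld)) / 86400
    s$depth <- ifelse(clamped, s$depth,
                      pmin(pmax(s$depth - wb * dt, 0), bottom))
  }
  s$depth <- dvm_clamp(s$depth, s$age, rules)

  ts <- sample_field(field, c("temp", "salt"), s$lon, s$lat, s$depth,
                     min(t + dt, max(field$time)))
  s$temp <- ts[, "temp"]; s$salt <- ts[, "salt"]

  ok <- is.finite(s$temp)
  s$fate[ok] <- thermal_fate(s$temp[ok], rules)

  still <- s$fate == "alive"
  if (any(still)) {
    onl <- land_at(field, s$lon[still], s$lat[still])
    inz <- rep(FALSE, sum(still))
    if (!is.null(zones) && any(onl)) {
      inz[onl] <- !is.na(point_in_zone(s$lon[still][onl],
                                       s$lat[still][onl], zones))
    }
    s$fate[still] <- beaching_fate(onl, s$age[still], inz, rules)
  }

  still <- s$fate == "alive"
  if (any(still)) {
    oob <- s$lon[still] < min(field$lon) | s$lon[still] > max(field$lon) |
      s$lat[still] < min(field$lat) | s$lat[still] > max(field$lat)
    s$fate[still][oob] <- "out_of_domain"
  }

  if (!is.null(zones)) {
    pre <- s$fate
    s <- settle_check(s, zones, rules)
    newly <- s$fate == "settled" & pre != "settled"
    s$settle_time[newly] <- t + dt
    s$settle_dps[newly] <- s$age[newly]
  }

  state[alive, ] <- s
  state
}

#' Run replicated larval dispersal simulations
#'
#' Runs `config$n_iterations` independent replicates of a release through
#' the field, recording every particle's position, sampled temperature and
#' salinity, and fate at the recording cadence (default 3 h). Replicates
#' differ only by their derived seeds; identical inputs and master seed give
#' byte-identical results.
#'
#' @param release A [release_stain()] result.
#' @param field An [ocean_field()] whose time axis covers the release time
#'   plus the configured duration.
#' @param rules A [bio_rules()].
#' @param zones Settlement zones or `NULL`.
#' @param config An [engine_config()].
#' @param schedule A [density_schedule()]; default loads the bundled one.
#' @return An object of class `ldm_run`: per-iteration trajectories
#'   (`time` vector plus `lon`, `lat`, `depth`, `temp`, `salt` record x
#'   particle matrices and an integer-coded `fate` matrix, legend in
#'   `fate_levels`), final states, and settlement records.
#' @export
run_simulation <- function(release, field, rules = bio_rules(), zones = NULL,
                           config = engine_config(),
                           schedule = density_schedule()) {
  t0 <- release$event$release_time
  t_end <- t0 + config$duration * 86400
  if (max(field$time) < t_end - 1e-6 || min(field$time) > t0 + 1e-6) {
    stop("field time span does not cover the simulation duration")
  }
  n_steps <- round(config$duration * 86400 / config$dt)
  rec_every <- round(config$record_interval / config$dt)
  rec_idx <- seq(0, n_steps, by = rec_every)
  n_rec <- length(rec_idx)
  n <- length(release$lon)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  iterations <- vector("list", config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    set.seed(iteration_seed(config$seed, it))
    state <- new_particle_state(release)
    ts0 <- sample_field(field, c("temp", "salt"), state$lon, state$lat,
                        state$depth, t0)
    state$temp <- ts0[, "temp"]; state$salt <- ts0[, "salt"]

    traj <- list(time = t0 + rec_idx * config$dt)
    for (v in c("lon", "lat", "depth", "temp", "salt")) {
      traj[[v]] <- matrix(NA_real_, n_rec, n)
    }
    traj$fate <- matrix(FATE_LEVELS[["alive"]], n_rec, n)
    record <- function(traj, k, state) {
      for (v in c("lon", "lat", "depth", "temp", "salt")) {
        traj[[v]][k, ] <- state[[v]]
      }
      traj$fate[k, ] <- unname(FATE_LEVELS[state$fate])
      traj
    }
    traj <- record(traj, 1L, state)
    k <- 1L
    for (stp in seq_len(n_steps)) {
      t <- t0 + (stp - 1) * config$dt
      state <- step_particles(state, field, zones, rules, config,
                              schedule, t)
      if (stp %% rec_every == 0) {
        k <- k + 1L
        traj <- record(traj, k, state)
      }
    }
    settled <- state[state$fate == "settled", ]
    settlement <- data.frame(
      iteration = rep(it, nrow(settled)), larva = settled$id,
      island = settled$settled_island, time = settled$settle_time,
      dps = settled$settle_dps, lon = settled$lon, lat = settled$lat)
    iterations[[it]] <- list(traj = traj, final = state,
                             settlement = settlement)
  }
  structure(list(iterations = iterations, config = config,
                 release = release, rules = rules,
                 fate_levels = FATE_LEVELS,
                 islands = if (!is.null(zones)) {
                   unique(vapply(zones, `[[`, "", "island"))
                 } else character()),
            class = "ldm_run")
}

#' Combined settlement table of a run
#'
#' @param run An `ldm_run`.
#' @return Data.frame with columns iteration, larva, island, time, dps,
#'   lon, lat (one row per settled larva across all iterations).
#' @export
settlement_table <- function(run) {
  stopifnot(inherits(run, "ldm_run"))
  do.call(rbind, lapply(run$iterations, `[[`, "settlement"))
}

#' @export
print.ldm_run <- function(x, ...) {
  st <- settlement_table(x)
  cat("<ldm_run>", length(x$iterations), "iterations x",
      ncol(x$iterations[[1]]$traj$lon), "particles,",
      nrow(x$iterations[[1]]$traj$lon), "records each\n")
  cat("  settled:", nrow(st), "larvae on",
      length(unique(st$island)), "island(s)\n")
  invisible(x)
}
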