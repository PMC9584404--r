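# Shared fixtures and independent oracles, built in code at test time.

# Two-layer tanh temperature profile; optional secondary deep step.
make_profile <- function(depths = seq(0, 200, 5), surface = 26, deep = 20,
                         thermocline = 50, thickness = 8, step2 = NULL) {
  temp <- (surface + deep) / 2 -
    (surface - deep) / 2 * tanh((depths - thermocline) / thickness)
  if (!is.null(step2)) {
    temp <- temp - step2$drop / 2 * (1 + tanh((depths - step2$depth) /
                                                step2$thickness))
  }
  data.frame(depth = depths, temp = temp)
}

# Small steady field: uniform current and/or gyre over a flat warm ocean.
make_test_field <- function(current = NULL, gyre = NULL, coast = NULL,
                            lon = seq(-78, -76, 0.05),
                            lat = seq(25, 27, 0.05),
                            depth = c(0, 25, 50, 75, 100, 150, 200),
                            days = 71, kz = 1e-5,
                            temperature = list(surface = 26, deep = 20,
                                               thermocline = 50,
                                               thickness = 8)) {
  render_field(
    field_scenario(current = current, gyre = gyre, coast = coast, kz = kz,
                   temperature = temperature),
    list(lon = lon, lat = lat, depth = depth, time = c(0, days * 86400)))
}

# Independent point-in-polygon oracle: textbook crossing-number ray cast
# (horizontal ray to +x), written without reference to the package's
# predicate. Boundary handling: points exactly on an edge/vertex are
# resolved by nudging the ray start; callers avoid boundary points.
pip_oracle <- function(px, py, ring) {
  n <- nrow(ring)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[j, 1]; y2 <- ring[j, 2]
    if ((y1 > py) != (y2 > py)) {
      x_at <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (x_at > px) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# Analytic solid-body rotation: exact particle position after time t for a
# vortex with angular velocity omega about (x0, y0), in local metres.
rotate_exact <- function(x, y, omega, t) {
  c(x * cos(omega * t) - y * sin(omega * t),
    x * sin(omega * t) + y * cos(omega * t))
}

# RK4 reference integrator for a velocity field given as a function
# (x, y) -> c(u, v), in local metres.
rk4_advect <- function(xy, vel, dt, n_steps) {
  for (s in seq_len(n_steps)) {
    k1 <- vel(xy)
    k2 <- vel(xy + dt / 2 * k1)
    k3 <- vel(xy + dt / 2 * k2)
    k4 <- vel(xy + dt * k3)
    xy <- xy + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  xy
}

# Write a temporary GeoJSON FeatureCollection of polygon zones.
write_geojson_zones <- function(zones, path = tempfile(fileext = ".geojson")) {
  feats <- lapply(zones, function(z) {
    ring <- rbind(z$ring, z$ring[1, ])
    coords <- lapply(seq_len(nrow(ring)), function(i) {
      c(ring[i, 1], ring[i, 2])
    })
    props <- list()
    if (!is.null(z$island)) props$island <- z$island
    if (!is.null(z$zone_id)) props$zone_id <- z$zone_id
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  writeLines(jsonlite::toJSON(list(type = "FeatureCollection",
                                   features = feats),
                              auto_unbox = TRUE, digits = NA), path)
  path
}

# Small complete run fixture: drifting release with a downstream zone.
make_small_run <- function(n_particles = 30, n_iterations = 2, days = 60,
                           seed = 11) {
  # 0.02 m/s drift puts particles 71-104 km downstream during days 41-60,
  # inside the zone band 65-110 km east of the release
  field <- make_test_field(current = list(speed = 0.02, bearing = 90),
                           days = days)
  ev <- spawning_event(lon = -77.8, lat = 26, n_particles = n_particles,
                       stain_radius = 5000)
  rel <- release_stain(ev, c(42, 150), seed = seed)
  zones <- rect_zone("Downstream", c(-77.15, -76.7), c(25.5, 26.5))
  cfg <- engine_config(dt = 10800, dgrid = 5500, umax = 0.3,
                       n_iterations = n_iterations, seed = seed,
                       duration = days)
  list(run = run_simulation(rel, field, bio_rules(), zones, cfg),
       field = field, release = rel, zones = zones, config = cfg)
}
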