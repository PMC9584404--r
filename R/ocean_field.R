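# Synthetic analytic ocean fields: construction, validation, diagnostics, I/O.

FIELD_VARS <- c("u", "v", "w", "temp", "salt", "kz")

#' Construct and validate a gridded 4-D ocean field
#'
#' An `ocean_field` bundles the hydrography a dispersing larva samples:
#' horizontal and vertical velocity, temperature, salinity and vertical
#' diffusivity on a regular (lon, lat, depth, time) grid, plus a land mask.
#' Depth is positive down with the surface at 0 m; vertical velocity `w`
#' follows the same positive-down convention. Land cells carry no finite
#' field values.
#'
#' @param lon,lat Strictly monotone axes in degrees east / degrees north.
#' @param depth Strictly increasing depth axis in metres, `depth[1] == 0`.
#' @param time Strictly increasing time axis in seconds since the simulation
#'   origin.
#' @param u,v East/north velocity (m/s), arrays of dim
#'   `c(nlon, nlat, ndepth, ntime)`.
#' @param w Vertical velocity (m/s, positive down), same dim.
#' @param temp,salt Temperature (degC) and salinity (PSU), same dim.
#' @param kz Vertical diffusivity (m^2/s), same dim.
#' @param landmask Logical `nlon x nlat` matrix, `TRUE` = land.
#' @param origin Optional character timestamp the time axis counts from
#'   (reporting only; the engine works in seconds).
#' @return A validated object of class `ocean_field`.
#' @export
ocean_field <- function(lon, lat, depth, time, u, v, w, temp, salt, kz,
                        landmask, origin = NULL) {
  fld <- structure(
    list(lon = as.numeric(lon), lat = as.numeric(lat),
         depth = as.numeric(depth), time = as.numeric(time),
         u = u, v = v, w = w, temp = temp, salt = salt, kz = kz,
         landmask = landmask, origin = origin,
         units = c(lon = "degrees_east", lat = "degrees_north",
                   depth = "m (positive down)", time = "s since origin",
                   u = "m s-1", v = "m s-1", w = "m s-1 (positive down)",
                   temp = "degC", salt = "PSU", kz = "m2 s-1")),
    class = "ocean_field")
  validate_field(fld)
}

#' @noRd
validate_field <- function(fld) {
  stopifnot(is.list(fld))
  missing <- setdiff(c("lon", "lat", "depth", "time", FIELD_VARS, "landmask"),
                     names(fld))
  if (length(missing)) {
    stop("ocean field is missing variable(s): ", paste(missing, collapse = ", "))
  }
  for (ax in c("lon", "lat", "depth", "time")) {
    d <- diff(fld[[ax]])
    if (length(fld[[ax]]) < 2 || any(d == 0) || (any(d > 0) && any(d < 0))) {
      stop("axis '", ax, "' must be strictly monotone with >= 2 points")
    }
  }
  if (fld$depth[1] != 0) stop("depth axis must start at the surface (0 m)")
  if (any(diff(fld$depth) < 0)) stop("depth axis must increase downward")
  shp <- c(length(fld$lon), length(fld$lat), length(fld$depth),
           length(fld$time))
  for (v in FIELD_VARS) {
    if (!identical(dim(fld[[v]]), as.integer(shp))) {
      stop("variable '", v, "' does not match the grid shape")
    }
  }
  if (!is.logical(fld$landmask) ||
      !identical(dim(fld$landmask), as.integer(shp[1:2]))) {
    stop("landmask must be a logical nlon x nlat matrix")
  }
  if (any(fld$landmask)) {
    land <- which(fld$landmask, arr.ind = TRUE)
    for (v in c("u", "v", "w")) {
      vals <- fld[[v]][cbind(land, 1L, 1L)]
      if (any(is.finite(vals))) {
        stop("land cells must not carry finite '", v, "' values")
      }
    }
  }
  fld
}

#' Describe an analytic ocean scenario
#'
#' A scenario is a composable recipe of named components that renders to a
#' valid [ocean_field()]: a uniform background current, a gyre (solid-body or
#' Rankine), a two-layer temperature profile with a thermocline (optionally a
#' secondary deep temperature step, useful for placing a below-thermocline
#' gradient maximum), a coastline (half-plane or circular island), constant
#' salinity, and a constant or depth-dependent vertical diffusivity.
#'
#' Gyres are rendered on a local f-plane (metre offsets frozen at the gyre
#' centre latitude) so rigid rotation is exactly divergence-free on the grid.
#'
#' @param current `list(speed, bearing)`: speed in m/s, bearing in degrees
#'   (direction of flow, 0 = north, 90 = east), or `NULL`.
#' @param gyre `list(lon, lat, radius, vmax, sense, profile)`: centre,
#'   radius (m), peak tangential speed (m/s) at the radius, sense (+1
#'   counterclockwise, -1 clockwise), profile `"solid"` (rigid rotation
#'   everywhere) or `"rankine"` (rigid core, 1/r decay outside), or `NULL`.
#' @param temperature `list(surface, deep, thermocline, thickness)` in degC /
#'   m; optional `step2 = list(depth, drop, thickness)` adds a second,
#'   weaker tanh step below the thermocline.
#' @param salinity Constant salinity, PSU.
#' @param coast `NULL`, a single coast spec, or a list of them:
#'   `list(type = "halfplane", side = "E"|"W"|"N"|"S", position = degrees)`
#'   (land on that side of the meridian/parallel) or
#'   `list(type = "island", lon, lat, radius)` with radius in metres.
#' @param kz Vertical diffusivity: a scalar (m^2/s) or a vector along the
#'   depth axis.
#' @return An object of class `field_scenario`.
#' @export
field_scenario <- function(current = NULL, gyre = NULL,
                           temperature = list(surface = 26, deep = 20,
                                              thermocline = 50, thickness = 10),
                           salinity = 36.2, coast = NULL, kz = 1e-5) {
  if (!is.null(gyre)) {
    if (!is.finite(gyre$radius) || gyre$radius <= 0) {
      stop("gyre radius must be positive")
    }
    gyre$sense <- gyre$sense %||% 1
    gyre$profile <- gyre$profile %||% "solid"
  }
  if (!is.null(coast) && !is.null(coast$type)) coast <- list(coast)
  structure(list(current = current, gyre = gyre, temperature = temperature,
                 salinity = salinity, coast = coast, kz = kz),
            class = "field_scenario")
}

#' Render a scenario onto a grid
#'
#' Deterministically evaluates every component of a [field_scenario()] on a
#' regular grid and returns the composite [ocean_field()]. Velocities from
#' multiple kinematic components add; land cells (from the coastline spec)
#' are masked with `NA` in every field variable.
#'
#' @param scenario A [field_scenario()].
#' @param grid `list(lon=, lat=, depth=, time=)` of axis vectors (degrees,
#'   degrees, metres positive-down starting at 0, seconds).
#' @param origin Optional origin timestamp passed through to the field.
#' @return An [ocean_field()].
#' @export
render_field <- function(scenario, grid, origin = NULL) {
  stopifnot(inherits(scenario, "field_scenario"))
  lon <- as.numeric(grid$lon); lat <- as.numeric(grid$lat)
  depth <- as.numeric(grid$depth); time <- as.numeric(grid$time)
  nlon <- length(lon); nlat <- length(lat)
  ndep <- length(depth); ntim <- length(time)
  shp <- c(nlon, nlat, ndep, ntim)

  u2 <- matrix(0, nlon, nlat)  # horizontal slices, replicated over depth/time
  v2 <- matrix(0, nlon, nlat)
  if (!is.null(scenario$current)) {
    br <- scenario$current$bearing * pi / 180
    u2 <- u2 + scenario$current$speed * sin(br)
    v2 <- v2 + scenario$current$speed * cos(br)
  }
  if (!is.null(scenario$gyre)) {
    g <- scenario$gyre
    x <- outer((lon - g$lon) * M_PER_DEG * cos(g$lat * pi / 180),
               rep(1, nlat))
    y <- outer(rep(1, nlon), (lat - g$lat) * M_PER_DEG)
    r <- sqrt(x^2 + y^2)
    omega <- g$vmax / g$radius
    if (identical(g$profile, "rankine")) {
      # tangential speed: omega*r inside the core, vmax*R/r outside
      vt_over_r <- ifelse(r <= g$radius, omega, g$vmax * g$radius / pmax(r, 1)^2)
    } else {
      vt_over_r <- omega
    }
    u2 <- u2 - g$sense * vt_over_r * y
    v2 <- v2 + g$sense * vt_over_r * x
  }

  tp <- scenario$temperature
  tz <- (tp$surface + tp$deep) / 2 -
    (tp$surface - tp$deep) / 2 * tanh((depth - tp$thermocline) / tp$thickness)
  if (!is.null(tp$step2)) {
    s2 <- tp$step2
    tz <- tz - s2$drop / 2 * (1 + tanh((depth - s2$depth) / s2$thickness))
  }

  kzz <- if (length(scenario$kz) == 1) rep(scenario$kz, ndep) else {
    stopifnot(length(scenario$kz) == ndep)
    as.numeric(scenario$kz)
  }

  landmask <- matrix(FALSE, nlon, nlat)
  for (cs in scenario$coast %||% list()) {
    if (cs$type == "halfplane") {
      landmask <- landmask | switch(cs$side,
        E = outer(lon >= cs$position, rep(TRUE, nlat)),
        W = outer(lon <= cs$position, rep(TRUE, nlat)),
        N = outer(rep(TRUE, nlon), lat >= cs$position),
        S = outer(rep(TRUE, nlon), lat <= cs$position),
        stop("unknown halfplane side: ", cs$side))
    } else if (cs$type == "island") {
      x <- outer((lon - cs$lon) * M_PER_DEG * cos(cs$lat * pi / 180),
                 rep(1, nlat))
      y <- outer(rep(1, nlon), (lat - cs$lat) * M_PER_DEG)
      landmask <- landmask | (sqrt(x^2 + y^2) <= cs$radius)
    } else {
      stop("unknown coast type: ", cs$type)
    }
  }

  expand_h <- function(m2) array(rep(m2, ndep * ntim), dim = shp)
  expand_z <- function(vz) array(rep(rep(vz, each = nlon * nlat), ntim),
                                 dim = shp)
  u <- expand_h(u2); v <- expand_h(v2)
  w <- array(0, dim = shp)
  temp <- expand_z(tz)
  salt <- array(scenario$salinity, dim = shp)
  kz <- expand_z(kzz)

  if (any(landmask)) {
    mask4 <- expand_h(ifelse(landmask, NA_real_, 1))
    u <- u * mask4; v <- v * mask4; w <- w * mask4
    temp <- temp * mask4; salt <- salt * mask4; kz <- kz * mask4
  }
  ocean_field(lon, lat, depth, time, u, v, w, temp, salt, kz, landmask,
              origin = origin)
}

# Locate x on a monotone-increasing axis: lower index and weight, clamped to
# the axis span (callers absorb out-of-domain particles before sampling).
#' @noRd
axis_locate <- function(x, axis) {
  n <- length(axis)
  i <- findInterval(x, axis, all.inside = TRUE)
  wgt <- (x - axis[i]) / (axis[i + 1] - axis[i])
  list(i = i, w = pmin(pmax(wgt, 0), 1))
}

#' Sample field variables at particle positions
#'
#' Tri-linear interpolation in (lon, lat, depth) and linear interpolation in
#' time, vectorized over particles. `NA` corners (land cells) contribute
#' nothing: velocities decay to zero toward the coast (zero-fill), while
#' scalars (temp, salt, kz) renormalize over wet corners so a particle in a
#' wet cell bordering land still samples finite hydrography.
#'
#' @param field An [ocean_field()].
#' @param vars Character vector of variable names among
#'   `u, v, w, temp, salt, kz`.
#' @param lon,lat,depth Particle coordinate vectors (recycled to a common
#'   length).
#' @param time Scalar or vector time in seconds; must lie within the field's
#'   time axis.
#' @return A numeric matrix, one row per particle, one column per variable.
#' @export
sample_field <- function(field, vars, lon, lat, depth, time) {
  n <- max(length(lon), length(lat), length(depth), length(time))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  depth <- rep_len(depth, n); time <- rep_len(time, n)
  if (any(time < min(field$time) - 1e-9 | time > max(field$time) + 1e-9)) {
    stop("sampling outside the field's time span")
  }
  lx <- axis_locate(lon, field$lon)
  ly <- axis_locate(lat, field$lat)
  lz <- axis_locate(depth, field$depth)
  lt <- axis_locate(time, field$time)

  out <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  corners <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1, dt = 0:1)
  for (v in vars) {
    arr <- field[[v]]
    zero_fill <- v %in% c("u", "v", "w")
    acc <- numeric(n)
    wtot <- numeric(n)
    for (k in seq_len(nrow(corners))) {
      cw <- corners[k, ]
      wk <- (if (cw$dx) lx$w else 1 - lx$w) *
            (if (cw$dy) ly$w else 1 - ly$w) *
            (if (cw$dz) lz$w else 1 - lz$w) *
            (if (cw$dt) lt$w else 1 - lt$w)
      vals <- arr[cbind(lx$i + cw$dx, ly$i + cw$dy, lz$i + cw$dz,
                        lt$i + cw$dt)]
      ok <- !is.na(vals)
      acc[ok] <- acc[ok] + wk[ok] * vals[ok]
      wtot[ok] <- wtot[ok] + wk[ok]
    }
    if (zero_fill) {
      out[, v] <- acc
    } else {
      out[, v] <- ifelse(wtot > 0, acc / wtot, NA_real_)
    }
  }
  out
}

#' Is a position over land?
#'
#' Land detection at the resolution of the model grid: a position is on land
#' iff the nearest grid cell (by axis distance) is masked.
#'
#' @param field An [ocean_field()].
#' @param lon,lat Position vectors.
#' @return Logical vector.
#' @export
land_at <- function(field, lon, lat) {
  ix <- pmin(pmax(round(approx(field$lon, seq_along(field$lon), xout = lon,
                               rule = 2)$y), 1), length(field$lon))
  iy <- pmin(pmax(round(approx(field$lat, seq_along(field$lat), xout = lat,
                               rule = 2)$y), 1), length(field$lat))
  field$landmask[cbind(ix, iy)]
}

#' Extract a temperature-depth profile from a field
#'
#' @param field An [ocean_field()].
#' @param lon,lat Scalar position.
#' @param time Scalar time in seconds (default: start of the time axis).
#' @return A data.frame with columns `depth` (m) and `temp` (degC).
#' @export
extract_profile <- function(field, lon, lat, time = field$time[1]) {
  temp <- sample_field(field, "temp", rep(lon, length(field$depth)),
                       rep(lat, length(field$depth)), field$depth, time)[, 1]
  data.frame(depth = field$depth, temp = temp)
}

#' @noRd
as_profile <- function(profile, temp = NULL) {
  if (!is.null(temp)) profile <- data.frame(depth = profile, temp = temp)
  stopifnot(all(c("depth", "temp") %in% names(profile)))
  profile <- profile[order(profile$depth), ]
  if (nrow(profile) < 3) stop("profile needs at least 3 depth levels")
  if (any(!is.finite(profile$temp))) stop("profile temperatures must be finite")
  profile
}

# Centred first-order temperature gradient at interior nodes.
#' @noRd
profile_gradient <- function(profile) {
  z <- profile$depth; tt <- profile$temp
  n <- length(z)
  i <- 2:(n - 1)
  data.frame(depth = z[i], grad = (tt[i + 1] - tt[i - 1]) / (z[i + 1] - z[i - 1]))
}

#' Thermocline depth of a temperature profile
#'
#' The thermocline is located at the depth where the magnitude of the
#' vertical temperature gradient, estimated by centred finite differences on
#' the native levels, is maximal; the node-level maximum is refined below
#' level spacing by a parabola through the three neighbouring gradient
#' ordinates. Ties are broken toward the shallower depth. A profile with no
#' distinct gradient maximum (isothermal, or a constant gradient throughout)
#' is an error, not a silent zero.
#'
#' @param profile A data.frame with columns `depth`, `temp`, or a depth
#'   vector when `temp` is given.
#' @param temp Optional temperature vector accompanying a depth vector.
#' @return Thermocline depth in metres.
#' @export
thermocline_depth <- function(profile, temp = NULL) {
  profile <- as_profile(profile, temp)
  g <- profile_gradient(profile)
  mag <- abs(g$grad)
  if (max(mag) < 1e-12 || (max(mag) - min(mag)) < 1e-9 * max(mag)) {
    stop("no distinct thermocline: temperature gradient has no interior maximum")
  }
  j <- which(mag >= max(mag) - 1e-12)[1]  # shallowest tie
  zj <- g$depth[j]
  if (j > 1 && j < nrow(g)) {
    z3 <- g$depth[(j - 1):(j + 1)]
    m3 <- mag[(j - 1):(j + 1)]
    denom <- (z3[1] - z3[2]) * (z3[1] - z3[3]) * (z3[2] - z3[3])
    # vertex of the interpolating parabola, clamped to the bracketing nodes
    a <- (z3[3] * (m3[2] - m3[1]) + z3[2] * (m3[1] - m3[3]) +
          z3[1] * (m3[3] - m3[2])) / denom
    b <- (z3[3]^2 * (m3[1] - m3[2]) + z3[2]^2 * (m3[3] - m3[1]) +
          z3[1]^2 * (m3[2] - m3[3])) / denom
    if (a < 0) zj <- min(max(-b / (2 * a), z3[1]), z3[3])
  }
  zj
}

#' Depth of the below-thermocline gradient maximum
#'
#' Locates the bottom extent of a thermocline-relative spawning release:
#' the depth strictly below the thermocline where the temperature-depth
#' gradient magnitude is maximal — the deviation from the consistent
#' decaying gradient where the rate of cooling grows again with depth.
#' Candidates are local maxima of the centred-difference gradient magnitude
#' (the thermocline's own monotonically decaying flank produces none);
#' among candidates the largest wins, ties broken toward the shallower
#' level. If the gradient decays monotonically all the way down (no
#' distinct deep feature), the first level below the thermocline — the
#' maximum of that decaying sequence — is returned.
#'
#' @inheritParams thermocline_depth
#' @param thermocline Thermocline depth in metres, within the profile span.
#' @return Depth in metres of an interior profile level.
#' @export
gradient_max_below <- function(profile, thermocline, temp = NULL) {
  profile <- as_profile(profile, temp)
  if (thermocline < min(profile$depth) || thermocline > max(profile$depth)) {
    stop("thermocline outside the profile depth span")
  }
  g <- profile_gradient(profile)
  z <- profile$depth
  # a node is "below" only if its centred stencil does not reach more than
  # half a level spacing above the thermocline (the thermocline's own node
  # must not masquerade as a deep gradient feature)
  i_int <- 2:(length(z) - 1)
  below <- g$depth > thermocline + 1e-9 &
    z[i_int - 1] >= thermocline - (z[i_int] - z[i_int - 1]) / 2 - 1e-9
  if (!any(g$depth > thermocline + 1e-9)) {
    stop("no profile levels below the thermocline")
  }
  if (!any(below)) below <- g$depth > thermocline + 1e-9
  mag <- abs(g$grad)
  n <- length(mag)
  up <- c(-Inf, mag[-n])    # neighbour above (sequence start counts)
  down <- c(mag[-1], -Inf)  # neighbour below
  local_max <- mag >= up - 1e-12 & mag >= down - 1e-12
  cand <- which(below & local_max)
  if (length(cand) == 0) {
    return(g$depth[which(below)[1]])
  }
  best <- cand[abs(g$grad[cand]) >= max(abs(g$grad[cand])) - 1e-12][1]
  g$depth[best]
}

#' Write / read an ocean field
#'
#' Fields are serialized to a single self-describing file (R serialization
#' of the validated `ocean_field` structure, including axis and unit
#' metadata). The round trip is lossless: every axis and array is reproduced
#' bit-for-bit, and files missing a required variable are rejected with the
#' variable named.
#'
#' @param field An [ocean_field()].
#' @param path File path.
#' @return `read_field` returns a validated [ocean_field()];
#'   `write_field` returns `path` invisibly.
#' @export
write_field <- function(field, path) {
  validate_field(field)
  saveRDS(unclass(field), path, version = 3)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("no such field file: ", path)
  raw <- readRDS(path)
  validate_field(structure(raw, class = "ocean_field"))
}

#' @export
print.ocean_field <- function(x, ...) {
  cat("<ocean_field> ",
      length(x$lon), "lon x", length(x$lat), "lat x",
      length(x$depth), "depth x", length(x$time), "time\n")
  cat("  lon  [", min(x$lon), ",", max(x$lon), "] degE\n")
  cat("  lat  [", min(x$lat), ",", max(x$lat), "] degN\n")
  cat("  depth[", min(x$depth), ",", max(x$depth), "] m (positive down)\n")
  cat("  time [", min(x$time), ",", max(x$time), "] s;",
      sum(x$landmask), "land cells\n")
  invisible(x)
}
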