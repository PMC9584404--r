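# Spawning-event parameterization: thermocline-relative depth range and the
# particle release "stain".

#' Describe an observed spawning event
#'
#' Holds the observations that parameterize a release: when and where the
#' spawn happened, the in-situ upper spawning-rush depth and in-situ
#' thermocline depth (whose ratio is translated onto the model water
#' column), the horizontal stain radius, and the particle count.
#'
#' @param release_time Release time in seconds on the simulation clock
#'   (numeric), or a POSIXct/ISO-8601 string resolved against `origin`.
#' @param lon,lat Release position, degrees.
#' @param insitu_upper_depth Observed upper spawning depth, metres
#'   (e.g. 63.7).
#' @param insitu_thermocline Observed in-situ thermocline depth, metres
#'   (e.g. 75.9).
#' @param stain_radius Horizontal release radius, metres (default 150,
#'   half the 300 m detection range of the telemetry tags).
#' @param n_particles Particles per release (default 10000).
#' @param origin Optional origin timestamp for non-numeric `release_time`.
#' @return An object of class `spawning_event`.
#' @export
spawning_event <- function(release_time = 0, lon, lat,
                           insitu_upper_depth = 63.7,
                           insitu_thermocline = 75.9,
                           stain_radius = 150, n_particles = 10000,
                           origin = NULL) {
  if (!is.numeric(release_time)) {
    stopifnot(!is.null(origin))
    release_time <- as.numeric(difftime(as.POSIXct(release_time, tz = "UTC"),
                                        as.POSIXct(origin, tz = "UTC"),
                                        units = "secs"))
  }
  stopifnot(insitu_upper_depth > 0, insitu_thermocline > 0,
            insitu_upper_depth <= insitu_thermocline,
            stain_radius > 0, n_particles > 0)
  structure(list(release_time = release_time, lon = lon, lat = lat,
                 insitu_upper_depth = insitu_upper_depth,
                 insitu_thermocline = insitu_thermocline,
                 stain_radius = stain_radius,
                 n_particles = as.integer(n_particles)),
            class = "spawning_event")
}

#' Translate an observed spawning event onto the model water column
#'
#' The upper release depth preserves the observed proportion between the
#' spawning depth and the thermocline: it is
#' `insitu_upper_depth / insitu_thermocline` times the model thermocline
#' depth (the ratio is carried at full precision, e.g. 63.7/75.9 = 0.8393...,
#' not a rounded 84%). The lower release depth is placed where the
#' temperature gradient magnitude is maximal below the model thermocline —
#' the depth at which the rate of cooling with depth grows again.
#'
#' @param event A [spawning_event()].
#' @param model_profile Temperature-depth data.frame for the model water
#'   column at the release site (see [extract_profile()]).
#' @return `c(upper, lower)` in metres.
#' @export
derive_depth_range <- function(event, model_profile) {
  tc <- thermocline_depth(model_profile)
  upper <- event$insitu_upper_depth / event$insitu_thermocline * tc
  lower <- gradient_max_below(model_profile, tc)
  if (upper >= lower) {
    stop("degenerate release range: upper (", round(upper, 2),
         " m) >= lower (", round(lower, 2), " m)")
  }
  c(upper = upper, lower = lower)
}

#' Sample the particle release stain
#'
#' Draws `n_particles` initial positions: depths uniform over the release
#' depth range (gamete release is modelled over the full ascent range), and
#' horizontal offsets area-uniform over the disc of `stain_radius` (radius
#' proportional to the square root of a uniform deviate). Reproducible for a
#' fixed seed.
#'
#' @param event A [spawning_event()].
#' @param depth_range `c(upper, lower)` metres, from [derive_depth_range()].
#' @param seed Integer RNG seed.
#' @return A `release_spec`: list with `lon`, `lat`, `depth` vectors, the
#'   depth range, the event, and the seed.
#' @export
release_stain <- function(event, depth_range, seed = 1L) {
  stopifnot(inherits(event, "spawning_event"),
            length(depth_range) == 2, depth_range[1] < depth_range[2])
  n <- event$n_particles
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  r <- event$stain_radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  depth <- runif(n, depth_range[1], depth_range[2])
  structure(list(
    lon = event$lon + r * cos(th) / (M_PER_DEG * cos(event$lat * pi / 180)),
    lat = event$lat + r * sin(th) / M_PER_DEG,
    depth = depth,
    upper_depth = unname(depth_range[1]),
    lower_depth = unname(depth_range[2]),
    event = event, seed = as.integer(seed)),
    class = "release_spec")
}

# Save/restore the global RNG state so seeded draws do not perturb callers.
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
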