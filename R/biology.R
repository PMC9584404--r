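# Larval biology: ontogenetic relative density and Stokes buoyancy, the
# diel-vertical-migration clamp, lethal temperatures, and onshore mortality.

#' Biological rule set for the larval individual-based model
#'
#' @param dvm_top Depth ceiling (m) enforced during the settlement competency
#'   period (diel vertical migration parameterized as "stay in the top 2 m").
#' @param competency `c(start, end)` of the settlement competency window in
#'   days post spawn (DPS); the end equals the pelagic larval duration.
#' @param lethal_cold,lethal_hot Lethal temperature bounds, degC. Bounds are
#'   strict: a larva survives at exactly 14 or 32 degC.
#' @param pld Pelagic larval duration, days.
#' @return An object of class `bio_rules`.
#' @export
bio_rules <- function(dvm_top = 2, competency = c(41, 71),
                      lethal_cold = 14, lethal_hot = 32, pld = 71) {
  stopifnot(dvm_top > 0, competency[1] > 0, competency[1] < competency[2],
            competency[2] == pld, lethal_cold < lethal_hot)
  structure(list(dvm_top = dvm_top, competency = as.numeric(competency),
                 lethal_cold = lethal_cold, lethal_hot = lethal_hot,
                 pld = pld),
            class = "bio_rules")
}

#' Ontogenetic relative-density schedule
#'
#' A two-column table mapping developmental progress (`age_fraction` =
#' age / pelagic larval duration, in [0, 1]) to the ratio of larval density
#' to seawater density at the upper thermocline. The mapping follows the
#' Anguilla japonica ontogeny transferred onto the bonefish larval duration;
#' ratios below 1 mean positive buoyancy. The bundled fixture
#' (`extdata/ajaponica_density_schedule_synthetic.tsv`) is a synthetic
#' reconstruction of that mapping — see its header — and any user table with
#' the same columns is accepted.
#'
#' @param table A data.frame with columns `age_fraction` and
#'   `density_ratio`, or a path to a delimited text file with those columns
#'   (`#` comments allowed). `NULL` loads the bundled synthetic schedule.
#' @return An object of class `density_schedule`.
#' @export
density_schedule <- function(table = NULL) {
  if (is.null(table)) {
    table <- system.file("extdata", "ajaponica_density_schedule_synthetic.tsv",
                         package = "leptoflow", mustWork = TRUE)
  }
  if (is.character(table)) {
    table <- read.delim(table, comment.char = "#")
  }
  stopifnot(all(c("age_fraction", "density_ratio") %in% names(table)))
  if (nrow(table) == 0) stop("density schedule table is empty")
  if (any(diff(table$age_fraction) <= 0)) {
    stop("age_fraction must be strictly increasing")
  }
  if (any(!is.finite(table$density_ratio)) ||
      any(table$density_ratio < 0.9 | table$density_ratio > 1.1)) {
    stop("density ratios must be finite and within the 0.9-1.1 sanity band")
  }
  structure(list(age_fraction = table$age_fraction,
                 density_ratio = table$density_ratio),
            class = "density_schedule")
}

#' Interpolate the relative density at a larval age
#'
#' Piecewise-linear interpolation of the schedule at `age / pld`, clamped to
#' the first/last tabulated ratios outside the tabulated range.
#'
#' @param schedule A [density_schedule()].
#' @param age Age in days post spawn (vectorized).
#' @param pld Pelagic larval duration in days.
#' @return Dimensionless density ratio(s).
#' @export
density_ratio <- function(schedule, age, pld = 71) {
  stopifnot(inherits(schedule, "density_schedule"), all(age >= 0))
  approx(schedule$age_fraction, schedule$density_ratio,
         xout = pmin(pmax(age / pld, 0), 1), rule = 2)$y
}

#' Stokes-law parameters for larval buoyancy
#'
#' @param radius Equivalent spherical radius, m. Default 1e-4 m: half the
#'   observed 2e-4 m head diameter of a hatchling (the drag-equivalent shape
#'   of a laterally compressed leptocephalus is ambiguous, so this is
#'   configurable).
#' @param viscosity Dynamic viscosity of seawater, Pa s.
#' @param water_density Seawater density, kg/m^3.
#' @param g Gravitational acceleration, m/s^2.
#' @return An object of class `stokes_params`.
#' @export
stokes_params <- function(radius = 1e-4, viscosity = 0.959e-3,
                          water_density = 1024.4, g = 9.81) {
  stopifnot(radius > 0, viscosity > 0, water_density > 0, g > 0)
  structure(list(radius = radius, viscosity = viscosity,
                 water_density = water_density, g = g),
            class = "stokes_params")
}

#' Stokes terminal buoyancy velocity
#'
#' Standard Stokes' law for a small sphere,
#' `w = (2/9) g r^2 (rho_w - rho_l) / mu`, converted to metres per day.
#' Positive values are upward (larva lighter than seawater); a ratio of 1
#' (neutral) gives 0.
#'
#' @param ratio Larva density / seawater density (dimensionless, see
#'   [density_ratio()]).
#' @param params A [stokes_params()].
#' @return Velocity in m/day, positive upward (vectorized over `ratio`).
#' @export
stokes_velocity <- function(ratio, params = stokes_params()) {
  stopifnot(inherits(params, "stokes_params"))
  rho_l <- ratio * params$water_density
  w_ms <- (2 / 9) * params$g * params$radius^2 *
    (params$water_density - rho_l) / params$viscosity
  w_ms * 86400
}

#' Diel-vertical-migration depth clamp
#'
#' During the settlement competency period (closed interval, default
#' [41, 71] DPS) larvae are held within the top `dvm_top` metres of the
#' water column, independent of proximity to settlement zones. Outside the
#' window the depth passes through unchanged.
#'
#' @param depth Depth vector, m.
#' @param age Age vector, DPS.
#' @param rules A [bio_rules()].
#' @return Clamped depth vector.
#' @export
dvm_clamp <- function(depth, age, rules = bio_rules()) {
  stopifnot(all(depth >= 0))
  competent <- age >= rules$competency[1] & age <= rules$competency[2]
  ifelse(competent, pmin(depth, rules$dvm_top), depth)
}

#' Thermal fate of a larva
#'
#' Strictly below the cold bound kills cold, strictly above the hot bound
#' kills hot; larvae survive at exactly the bounds.
#'
#' @param temp Sampled temperature vector, degC.
#' @param rules A [bio_rules()].
#' @return Character vector: `"alive"`, `"dead_cold"` or `"dead_hot"`.
#' @export
thermal_fate <- function(temp, rules = bio_rules()) {
  stopifnot(all(is.finite(temp)))
  ifelse(temp < rules$lethal_cold, "dead_cold",
         ifelse(temp > rules$lethal_hot, "dead_hot", "alive"))
}

#' Onshore-mortality (beaching) fate
#'
#' A particle contacting a land cell before settlement competency dies of
#' onshore mortality (the life stage-habitat mismatch stand-in). A competent
#' larva contacting land outside any settlement zone also beaches
#' (settlement inside zones is adjudicated separately by [settle_check()]).
#'
#' @param on_land Logical vector: is the particle's cell land?
#' @param age Age vector, DPS.
#' @param in_zone Logical vector: is the position inside a settlement zone?
#' @param rules A [bio_rules()].
#' @return Character vector: `"alive"` or `"dead_beached"`.
#' @export
beaching_fate <- function(on_land, age, in_zone = FALSE, rules = bio_rules()) {
  stopifnot(all(age >= 0))
  n <- max(length(on_land), length(age), length(in_zone))
  on_land <- rep_len(on_land, n); age <- rep_len(age, n)
  in_zone <- rep_len(in_zone, n)
  pre <- age < rules$competency[1]
  beaches <- on_land & (pre | !in_zone)
  ifelse(beaches, "dead_beached", "alive")
}
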