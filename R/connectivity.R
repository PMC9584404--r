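# Assessment layer: fate proportions, gridded densities, settlement KDE,
# connectivity matrices, footprints, dispersal geometry, and per-larva
# development-environment summaries.

EARTH_RADIUS_M <- 6371000

#' Daily mean fate proportions across iterations
#'
#' For each whole day of the dispersal period, the across-iteration mean of
#' the proportion of released larvae carrying each fate. Proportions sum to
#' one at every day (fates are exclusive and exhaustive).
#'
#' @param run An `ldm_run` from [run_simulation()].
#' @return A data.frame with columns `day`, `fate`, `proportion`.
#' @export
fate_proportions <- function(run) {
  stopifnot(inherits(run, "ldm_run"), length(run$iterations) >= 1)
  t0 <- run$iterations[[1]]$traj$time[1]
  rec_days <- (run$iterations[[1]]$traj$time - t0) / 86400
  day_rows <- which(abs(rec_days - round(rec_days)) < 1e-9)
  fates <- names(run$fate_levels)
  per_iter <- lapply(run$iterations, function(it) {
    f <- it$traj$fate[day_rows, , drop = FALSE]
    sapply(run$fate_levels, function(code) rowMeans(f == code))
  })
  mean_prop <- Reduce(`+`, per_iter) / length(per_iter)
  data.frame(day = rep(rec_days[day_rows], times = length(fates)),
             fate = rep(fates, each = length(day_rows)),
             proportion = as.vector(mean_prop))
}

# Which (record, particle) observations are "in-domain": every record while
# alive, plus the first record of an in-domain absorbing fate (beached,
# cold, hot, settled). Out-of-domain records never count.
#' @noRd
in_domain_records <- function(fate_mat) {
  n_rec <- nrow(fate_mat)
  prev <- rbind(matrix(FATE_LEVELS[["alive"]], 1, ncol(fate_mat)),
                fate_mat[-n_rec, , drop = FALSE])
  (fate_mat == FATE_LEVELS[["alive"]]) |
    (fate_mat >= FATE_LEVELS[["dead_beached"]] &
       prev == FATE_LEVELS[["alive"]])
}

#' Gridded larval occupancy density
#'
#' Exact per-cell occupancy counts of trajectory records, either over all
#' timesteps (dispersal-pathway density) or at the final timestep only
#' (end-of-PLD positions). All-steps mode counts every record while a larva
#' is alive plus the record at which an in-domain absorbing fate (beached,
#' cold, hot, settled) is assigned; final-step mode counts each larva still
#' in the domain at its last recorded position. A natural-log transform of
#' the counts is included for display.
#'
#' @param run An `ldm_run`.
#' @param lon_breaks,lat_breaks Cell edge vectors covering the domain.
#' @param mode `"all"` or `"final"`.
#' @return A list with `lon_breaks`, `lat_breaks`, integer matrix `counts`
#'   (lon cell x lat cell), `log_counts` (`log(counts)`, `-Inf` where
#'   empty), and `n_records`, the total count.
#' @export
gridded_density <- function(run, lon_breaks, lat_breaks,
                            mode = c("all", "final")) {
  mode <- match.arg(mode)
  stopifnot(inherits(run, "ldm_run"))
  counts <- matrix(0L, length(lon_breaks) - 1, length(lat_breaks) - 1)
  for (it in run$iterations) {
    f <- it$traj$fate
    if (mode == "all") {
      keep <- in_domain_records(f)
      lon <- it$traj$lon[keep]; lat <- it$traj$lat[keep]
    } else {
      last <- nrow(f)
      keep <- f[last, ] != FATE_LEVELS[["out_of_domain"]]
      lon <- it$traj$lon[last, keep]; lat <- it$traj$lat[last, keep]
    }
    ix <- findInterval(lon, lon_breaks, rightmost.closed = TRUE)
    iy <- findInterval(lat, lat_breaks, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= nrow(counts) & iy >= 1 & iy <= ncol(counts)
    if (any(ok)) {
      tab <- table(factor(ix[ok], levels = seq_len(nrow(counts))),
                   factor(iy[ok], levels = seq_len(ncol(counts))))
      counts <- counts + unclass(tab)
    }
  }
  list(lon_breaks = lon_breaks, lat_breaks = lat_breaks,
       counts = counts, log_counts = log(counts),
       n_records = sum(counts), mode = mode)
}

#' Great-circle path length of a track
#'
#' Sum of haversine segment lengths between consecutive records, on a
#' sphere of radius 6371 km.
#'
#' @param lon,lat Track coordinate vectors (>= 2 records).
#' @return Path length in km.
#' @export
path_length <- function(lon, lat) {
  stopifnot(length(lon) >= 2, length(lon) == length(lat))
  p <- cbind(lon, lat)
  sum(geosphere::distHaversine(p[-nrow(p), , drop = FALSE],
                               p[-1, , drop = FALSE],
                               r = EARTH_RADIUS_M)) / 1000
}

#' Coefficient of dispersal of a settled larva's track
#'
#' The ratio of the straight-line (great-circle) distance from the spawning
#' location to the settlement location over the along-track dispersal path
#' length. Values near 1 indicate linear transport; values near 0 indicate
#' circuitous, retained dispersal. Lies in (0, 1] by the triangle
#' inequality.
#'
#' @param lon,lat Track coordinates from release to settlement (>= 2
#'   records).
#' @return Dimensionless ratio in (0, 1].
#' @export
coefficient_of_dispersal <- function(lon, lat) {
  n <- length(lon)
  path <- path_length(lon, lat)
  if (path <= 0) stop("zero path length: coefficient of dispersal undefined")
  chord <- geosphere::distHaversine(c(lon[1], lat[1]), c(lon[n], lat[n]),
                                    r = EARTH_RADIUS_M) / 1000
  min(chord / path, 1)
}

#' Settlement kernel density estimate, normalized to a maximum of one
#'
#' 2-D Gaussian-kernel density of settlement positions on a lon/lat grid
#' (via [MASS::kde2d()]), divided by its maximum so the surface peaks at
#' exactly 1. Bandwidth defaults to the normal-reference rule per axis.
#'
#' @param lon,lat Settlement position vectors (>= 1 point).
#' @param bandwidth Optional length-2 bandwidth (degrees); default
#'   normal-reference per axis, with a small floor for degenerate spreads.
#' @param gridsize Grid points per axis.
#' @param lims Optional `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return A list with `x`, `y`, `z` (normalized, max exactly 1), `z_raw`
#'   (the density, integrating to ~1), and `n_points`.
#' @export
settlement_kde <- function(lon, lat, bandwidth = NULL, gridsize = 101,
                           lims = NULL) {
  n <- length(lon)
  if (n < 1) stop("settlement KDE needs at least one point")
  if (is.null(bandwidth)) {
    bw1 <- if (n >= 2) MASS::bandwidth.nrd(lon) else 0
    bw2 <- if (n >= 2) MASS::bandwidth.nrd(lat) else 0
    bandwidth <- pmax(c(bw1, bw2), 0.05)
  }
  if (is.null(lims)) {
    pad <- 3 * max(bandwidth)
    lims <- c(range(lon) + c(-pad, pad), range(lat) + c(-pad, pad))
  }
  kd <- MASS::kde2d(lon, lat, h = bandwidth, n = gridsize, lims = lims)
  list(x = kd$x, y = kd$y, z = kd$z / max(kd$z), z_raw = kd$z,
       n_points = n, bandwidth = bandwidth)
}

#' Island connectivity matrix
#'
#' Aggregates settlement records into per-island totals (settled larvae
#' across all iterations, natural-log displayed in the figures) and the
#' fraction of iterations that delivered at least one settler to each
#' island.
#'
#' @param records Settlement table (see [settlement_table()]).
#' @param n_iterations Number of iterations in the run.
#' @param islands Optional island labels to include (zero rows for islands
#'   never settled).
#' @return Data.frame with columns `island`, `n_settled`,
#'   `iteration_fraction`.
#' @export
connectivity_matrix <- function(records, n_iterations, islands = NULL) {
  stopifnot(n_iterations >= 1)
  if (nrow(records) > 0 &&
      (any(records$iteration < 1) || any(records$iteration > n_iterations))) {
    stop("settlement records reference iterations outside 1..n_iterations")
  }
  islands <- islands %||% sort(unique(records$island))
  n_settled <- vapply(islands, function(isl) {
    sum(records$island == isl)
  }, integer(1))
  frac <- vapply(islands, function(isl) {
    length(unique(records$iteration[records$island == isl])) / n_iterations
  }, numeric(1))
  data.frame(island = islands, n_settled = n_settled,
             iteration_fraction = frac, row.names = NULL)
}

#' Settlement footprints and their frequencies
#'
#' A footprint is the set of islands settled within one iteration. Returns
#' every observed footprint (iterations with no settlement contribute the
#' empty footprint, labelled `"(none)"`) with its relative frequency;
#' frequencies sum to 1 over iterations.
#'
#' @inheritParams connectivity_matrix
#' @return Data.frame with columns `footprint` (island names sorted and
#'   joined by `" + "`), `n_iterations`, `frequency`, sorted by decreasing
#'   frequency.
#' @export
settlement_footprints <- function(records, n_iterations) {
  stopifnot(n_iterations >= 1)
  fp <- vapply(seq_len(n_iterations), function(it) {
    isl <- sort(unique(records$island[records$iteration == it]))
    if (length(isl) == 0) "(none)" else paste(isl, collapse = " + ")
  }, character(1))
  tab <- sort(table(fp), decreasing = TRUE)
  data.frame(footprint = names(tab), n_iterations = as.integer(tab),
             frequency = as.numeric(tab) / n_iterations, row.names = NULL)
}

#' Per-larva development-environment summaries
#'
#' For every successfully settled larva, summarizes its dispersal history
#' from release to settlement (inclusive): coefficient of dispersal,
#' settlement DPS, mean/min/max temperature and salinity, release depth,
#' and mean dispersal depth.
#'
#' @param run An `ldm_run`.
#' @return Data.frame, one row per settled larva, with columns `iteration`,
#'   `larva`, `island`, `coefficient`, `dps`, `path_km`, `temp_mean`,
#'   `temp_min`, `temp_max`, `salt_mean`, `salt_min`, `salt_max`,
#'   `release_depth`, `mean_depth`.
#' @export
dev_env_records <- function(run) {
  stopifnot(inherits(run, "ldm_run"))
  rows <- list()
  for (it_idx in seq_along(run$iterations)) {
    it <- run$iterations[[it_idx]]
    st <- it$settlement
    if (nrow(st) == 0) next
    for (r in seq_len(nrow(st))) {
      id <- st$larva[r]
      k <- max(which(it$traj$time <= st$time[r] + 1e-6))
      lon <- it$traj$lon[1:k, id]; lat <- it$traj$lat[1:k, id]
      temp <- it$traj$temp[1:k, id]; salt <- it$traj$salt[1:k, id]
      depth <- it$traj$depth[1:k, id]
      rows[[length(rows) + 1]] <- data.frame(
        iteration = it_idx, larva = id, island = st$island[r],
        coefficient = coefficient_of_dispersal(lon, lat),
        dps = st$dps[r], path_km = path_length(lon, lat),
        temp_mean = mean(temp, na.rm = TRUE),
        temp_min = min(temp, na.rm = TRUE),
        temp_max = max(temp, na.rm = TRUE),
        salt_mean = mean(salt, na.rm = TRUE),
        salt_min = min(salt, na.rm = TRUE),
        salt_max = max(salt, na.rm = TRUE),
        release_depth = depth[1], mean_depth = mean(depth))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(iteration = integer(), larva = integer(),
                      island = character(), coefficient = numeric(),
                      dps = numeric(), path_km = numeric(),
                      temp_mean = numeric(), temp_min = numeric(),
                      temp_max = numeric(), salt_mean = numeric(),
                      salt_min = numeric(), salt_max = numeric(),
                      release_depth = numeric(), mean_depth = numeric()))
  }
  do.call(rbind, rows)
}
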