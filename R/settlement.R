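# Settlement zones: GeoJSON polygons tagged with island names, the
# containment predicate, and the competency-window settlement rule.

#' Load settlement zones from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of Polygon/MultiPolygon features, each
#' carrying an `island` property (the grouping label used by the
#' connectivity statistics) and optionally a `zone_id`. Rings are validated
#' to be simple (non-self-intersecting); offending features are rejected by
#' index.
#'
#' @param path Path to a GeoJSON file (WGS84 lon/lat).
#' @return An object of class `settlement_zones`: a list of zones, each with
#'   `zone_id`, `island`, and `rings` (list of two-column lon/lat matrices;
#'   the first ring of each polygon is the outer boundary, later rings are
#'   holes under the even-odd rule).
#' @export
load_zones <- function(path) {
  if (!file.exists(path)) stop("no such zones file: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("zones file must be a GeoJSON FeatureCollection")
  }
  zones <- lapply(seq_along(gj$features), function(i) {
    ft <- gj$features[[i]]
    island <- ft$properties$island
    if (is.null(island) || !nzchar(island)) {
      stop("feature ", i, " has no 'island' property")
    }
    geom <- ft$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("feature ", i, " has unsupported geometry type: ", geom$type))
    rings <- list()
    for (poly in polys) {
      for (ring in poly) {
        m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
        # drop the GeoJSON closing vertex; we treat rings as implicitly closed
        if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) {
          m <- m[-nrow(m), , drop = FALSE]
        }
        if (nrow(m) < 3) stop("feature ", i, " has a ring with < 3 vertices")
        if (ring_self_intersects(m)) {
          stop("feature ", i, " has a self-intersecting ring")
        }
        rings[[length(rings) + 1]] <- m
      }
    }
    list(zone_id = ft$properties$zone_id %||% paste0("zone", i),
         island = island, rings = rings)
  })
  structure(zones, class = "settlement_zones")
}

#' @rdname load_zones
#' @param zones A `settlement_zones` object.
#' @export
write_zones <- function(zones, path) {
  feats <- lapply(zones, function(z) {
    coords <- lapply(z$rings, function(m) {
      m <- rbind(m, m[1, ])  # close the ring
      lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    })
    list(type = "Feature",
         properties = list(island = z$island, zone_id = z$zone_id),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  json <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                           auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

# O(n^2) simplicity check; zone rings are small polygons.
#' @noRd
ring_self_intersects <- function(m) {
  n <- nrow(m)
  seg <- cbind(m, m[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip segments adjacent to i
    for (j in js) {
      if (segments_cross(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

#' @noRd
segments_cross <- function(a, b) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  p1 <- a[1:2]; p2 <- a[3:4]; p3 <- b[1:2]; p4 <- b[3:4]
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
   ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

# Even-odd containment for one ring, vectorized over points.
#' @noRd
pip_ring <- function(px, py, ring) {
  xs <- ring[, 1]; ys <- ring[, 2]
  n <- length(xs)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Is a point on a ring's boundary (within eps, degrees)?
#' @noRd
on_ring_boundary <- function(px, py, ring, eps = 1e-12) {
  xs <- ring[, 1]; ys <- ring[, 2]
  n <- length(xs)
  on <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    dx <- xs[i] - xs[j]; dy <- ys[i] - ys[j]
    len2 <- dx^2 + dy^2
    t <- if (len2 > 0) ((px - xs[j]) * dx + (py - ys[j]) * dy) / len2 else 0
    t <- pmin(pmax(t, 0), 1)
    qx <- xs[j] + t * dx; qy <- ys[j] + t * dy
    on <- on | ((px - qx)^2 + (py - qy)^2 <= eps^2 * (1 + len2))
    j <- i
  }
  on
}

#' Assign positions to settlement zones
#'
#' Even-odd (ray-casting) containment with boundary points counting as
#' inside (zones are deliberately over-extended beyond the shoreline, so the
#' closed-polygon convention favours settlement). Overlapping zones resolve
#' to the first containing zone in file order.
#'
#' @param lon,lat Position vectors.
#' @param zones A [load_zones()] result.
#' @return Character vector of island names, `NA` where outside all zones.
#' @export
point_in_zone <- function(lon, lat, zones) {
  stopifnot(inherits(zones, "settlement_zones"))
  out <- rep(NA_character_, length(lon))
  todo <- rep(TRUE, length(lon))
  for (z in zones) {
    if (!any(todo)) break
    inside <- rep(FALSE, sum(todo))
    px <- lon[todo]; py <- lat[todo]
    for (ring in z$rings) {
      inside <- xor(inside, pip_ring(px, py, ring))
      inside <- inside | on_ring_boundary(px, py, ring)
    }
    hit <- which(todo)[inside]
    out[hit] <- z$island
    todo[hit] <- FALSE
  }
  out
}

#' Apply the settlement rule to particle states
#'
#' An alive larva whose age lies in the settlement competency window
#' (closed, default 41-71 DPS) and whose position falls inside a settlement
#' zone settles on that zone's island; settlement is absorbing. In-zone
#' presence before competency has no effect (only land contact kills
#' pre-competent larvae).
#'
#' @param state A data.frame with columns `lon`, `lat`, `age` (DPS), `fate`,
#'   and `settled_island`.
#' @param zones A [load_zones()] result.
#' @param rules A [bio_rules()].
#' @return `state` with settled rows updated.
#' @export
settle_check <- function(state, zones, rules = bio_rules()) {
  cand <- state$fate == "alive" &
    state$age >= rules$competency[1] & state$age <= rules$competency[2]
  if (any(cand)) {
    island <- point_in_zone(state$lon[cand], state$lat[cand], zones)
    hit <- !is.na(island)
    idx <- which(cand)[hit]
    state$fate[idx] <- "settled"
    state$settled_island[idx] <- island[hit]
  }
  state
}

#' Build a rectangular settlement zone
#'
#' Convenience constructor for synthetic scenarios and tests: an axis-aligned
#' lon/lat box as a single-ring zone.
#'
#' @param island Island label.
#' @param lon_range,lat_range Numeric length-2 ranges, degrees.
#' @param zone_id Optional id.
#' @return A `settlement_zones` object with one zone.
#' @export
rect_zone <- function(island, lon_range, lat_range, zone_id = island) {
  ring <- cbind(lon = c(lon_range[1], lon_range[2], lon_range[2], lon_range[1]),
                lat = c(lat_range[1], lat_range[1], lat_range[2], lat_range[2]))
  structure(list(list(zone_id = zone_id, island = island, rings = list(ring))),
            class = "settlement_zones")
}

#' Concatenate settlement zones
#' @param ... `settlement_zones` objects.
#' @return A combined `settlement_zones` object preserving order.
#' @export
c_zones <- function(...) {
  structure(do.call(c, lapply(list(...), unclass)), class = "settlement_zones")
}
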