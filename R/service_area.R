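# WGS84 ellipsoid constants
WGS84_A <- 6378137
WGS84_F <- 1 / 298.257223563
WGS84_E2 <- WGS84_F * (2 - WGS84_F)

check_coords <- function(lat, lon) {
  ok <- is.na(lat) | is.na(lon) |
    (lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180)
  if (!all(ok))
    stop("coordinates out of range: latitude must be in [-90,90], longitude in [-180,180]",
         call. = FALSE)
}

#' Geodesic distance on the WGS84 ellipsoid
#'
#' Shortest-path (geodesic) distance between points on the WGS84 ellipsoid,
#' in kilometres. Vectorised over both arguments.
#'
#' @param lat1,lon1,lat2,lon2 WGS84 decimal degrees.
#' @return Numeric vector of kilometres.
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1); check_coords(lat2, lon2)
  geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

#' Filter the farthest missions from a base
#'
#' Missions whose geodesic distance from the base exceeds the per-base
#' distance quantile (default the 95th percentile, linear interpolation
#' between order statistics) are treated as outliers and removed before
#' hull construction; ties at the cutoff are retained.
#'
#' @param points `data.frame` with `latitude`, `longitude`.
#' @param base A [base_definition()].
#' @param quantile Retained fraction cutoff (default 0.95).
#' @return The retained rows, with attributes `cutoff_km` (the percentile)
#'   and `distance_km` (distances of the retained rows).
#' @export
filter_distance_outliers <- function(points, base, quantile = 0.95) {
  if (nrow(points) == 0L)
    stop("point list must be non-empty", call. = FALSE)
  d <- geodesic_distance(points$latitude, points$longitude,
                         base$latitude, base$longitude)
  cutoff <- stats::quantile(d, quantile, type = 7, names = FALSE)
  keep <- d <= cutoff
  out <- points[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff_km") <- cutoff
  attr(out, "distance_km") <- d[keep]
  out
}

# azimuthal equidistant projection about a centre: geodesic distance and
# azimuth from the centre become polar coordinates in a local plane (metres)
aeqd_project <- function(points, center_lat, center_lon) {
  inv <- geosphere::geodesic_inverse(cbind(center_lon, center_lat),
                                     cbind(points$longitude,
                                           points$latitude))
  az <- inv[, "azimuth1"] * pi / 180
  cbind(x = inv[, "distance"] * sin(az), y = inv[, "distance"] * cos(az))
}

#' Convex hull of geographic points
#'
#' Points are projected into an azimuthal equidistant plane centred on
#' `center` (default: the base; otherwise the points' mean position), the
#' planar convex hull is taken, and the hull vertices — a subset of the
#' input points — are returned in ring order as geographic coordinates. At
#' the few-hundred-kilometre scale of HEMS service areas the discrepancy
#' against a true geodesic hull is negligible.
#'
#' @param points `data.frame` with `latitude`, `longitude` (`>= 3`
#'   non-collinear points for a polygon).
#' @param center Optional `c(latitude, longitude)` projection centre.
#' @return `data.frame` of hull vertices (open ring, counter-clockwise) with
#'   attribute `degenerate = TRUE` when fewer than 3 distinct non-collinear
#'   points were supplied (such a ring has zero area).
#' @export
convex_hull <- function(points, center = NULL) {
  check_coords(points$latitude, points$longitude)
  pts <- unique(points[, c("latitude", "longitude")])
  if (is.null(center))
    center <- c(mean(pts$latitude), mean(pts$longitude))
  if (nrow(pts) < 3L) {
    out <- pts; rownames(out) <- NULL
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  xy <- aeqd_project(pts, center[1], center[2])
  idx <- rev(grDevices::chull(xy))      # chull is clockwise; reverse to CCW
  out <- pts[idx, , drop = FALSE]
  rownames(out) <- NULL
  # collinear input: chull may return 2 points, or a zero-area ring
  if (nrow(out) < 3L) attr(out, "degenerate") <- TRUE
  out
}

# authalic latitude (radians) of geodetic latitude in degrees: maps the
# ellipsoid to the equal-area sphere of radius authalic_radius()
authalic_lat <- function(lat_deg) {
  e <- sqrt(WGS84_E2)
  q <- function(phi) {
    s <- sin(phi)
    (1 - WGS84_E2) * (s / (1 - WGS84_E2 * s^2) -
                        (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
  }
  qp <- q(pi / 2)
  asin(pmin(1, pmax(-1, q(lat_deg * pi / 180) / qp)))
}

authalic_radius <- function() {
  e <- sqrt(WGS84_E2)
  s <- 1
  qp <- (1 - WGS84_E2) * (s / (1 - WGS84_E2) -
                            (1 / (2 * e)) * log((1 - e) / (1 + e)))
  WGS84_A * sqrt(qp / 2)
}

# Lambert azimuthal equal-area projection (on the authalic sphere) of
# lat/lon degrees about a centre; returns metres
laea_project <- function(lat, lon, c_lat, c_lon) {
  R <- authalic_radius()
  b <- authalic_lat(lat); b0 <- authalic_lat(c_lat)
  dl <- (lon - c_lon) * pi / 180
  denom <- 1 + sin(b0) * sin(b) + cos(b0) * cos(b) * cos(dl)
  kp <- sqrt(2 / denom)
  cbind(x = R * kp * cos(b) * sin(dl),
        y = R * kp * (cos(b0) * sin(b) - sin(b0) * cos(b) * cos(dl)))
}

# proper segment-intersection test for a closed ring (O(n^2), rings are
# small); convex rings never trigger it, but malformed input is refused
ring_self_intersects <- function(xy) {
  n <- nrow(xy)
  if (n < 4L) return(FALSE)
  seg <- function(i) rbind(xy[i, ], xy[i %% n + 1L, ])
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 2L)) for (j in (i + 2L):n) {
    if (i == 1L && j == n) next
    s1 <- seg(i); s2 <- seg(j)
    d1 <- cross(s2[1, ], s2[2, ], s1[1, ]); d2 <- cross(s2[1, ], s2[2, ], s1[2, ])
    d3 <- cross(s1[1, ], s1[2, ], s2[1, ]); d4 <- cross(s1[1, ], s1[2, ], s2[2, ])
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  }
  FALSE
}

#' Area of a geographic ring in square kilometres
#'
#' The ring is projected with a Lambert azimuthal equal-area projection (on
#' the authalic sphere of the WGS84 ellipsoid) centred on the ring's mean
#' position, and the planar shoelace formula is applied. Equal-area
#' projection makes the result independent of hemisphere and starting
#' vertex. Degenerate rings (< 3 vertices) have area 0; a self-intersecting
#' ring is refused (cannot arise from [convex_hull()]).
#'
#' @param ring `data.frame` of vertices with `latitude`, `longitude`
#'   (open ring: first vertex not repeated).
#' @return Area in km².
#' @export
hull_area_km2 <- function(ring) {
  if (is.null(ring) || nrow(ring) < 3L) return(0)
  check_coords(ring$latitude, ring$longitude)
  xy <- laea_project(ring$latitude, ring$longitude,
                     mean(ring$latitude), mean(ring$longitude))
  if (ring_self_intersects(xy))
    stop("ring is self-intersecting", call. = FALSE)
  n <- nrow(xy)
  j <- c(2:n, 1L)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2 / 1e6
}

#' Point-in-convex-ring test
#'
#' TRUE when each point lies inside or on the (counter-clockwise) convex
#' ring, within a small projected tolerance.
#'
#' @param points,ring `data.frame`s with `latitude`, `longitude`.
#' @param tol_m Tolerance in metres (default ~1e-6 degree).
#' @return Logical vector.
#' @export
points_in_hull <- function(points, ring, tol_m = 0.15) {
  if (nrow(ring) < 3L) return(rep(FALSE, nrow(points)))
  c_lat <- mean(ring$latitude); c_lon <- mean(ring$longitude)
  rxy <- aeqd_project(ring, c_lat, c_lon)
  pxy <- aeqd_project(points, c_lat, c_lon)
  n <- nrow(rxy)
  inside <- rep(TRUE, nrow(pxy))
  for (i in seq_len(n)) {
    a <- rxy[i, ]; b <- rxy[i %% n + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    len <- sqrt(ex^2 + ey^2)
    s <- (ex * (pxy[, 2] - a[2]) - ey * (pxy[, 1] - a[1])) / max(len, 1e-12)
    inside <- inside & (s >= -tol_m)
  }
  inside
}

#' Per-base, per-period service-area summary
#'
#' Applies the distance filter, builds the hull, and computes its area plus
#' the median and interquartile range of the geodesic mission distances.
#' Median and IQR are computed on all supplied (map-eligible) missions; the
#' hull uses only the distance-filtered subset.
#'
#' @param points Mission locations (`latitude`, `longitude`).
#' @param base A [base_definition()].
#' @param period `"pre"` or `"post"`.
#' @param quantile Distance-filter quantile (default 0.95).
#' @return An object of class `hull_result`.
#' @export
hull_result <- function(points, base, period, quantile = 0.95) {
  retained <- filter_distance_outliers(points, base, quantile)
  ring <- convex_hull(retained, center = c(base$latitude, base$longitude))
  d_all <- geodesic_distance(points$latitude, points$longitude,
                             base$latitude, base$longitude)
  structure(list(
    base_id = base$base_id, period = period,
    n_input = nrow(points), n_retained = nrow(retained),
    hull_vertices = ring, area_km2 = hull_area_km2(ring),
    median_distance_km = stats::median(d_all),
    iqr_distance_km = stats::IQR(d_all),
    distances_km = d_all, cutoff_km = attr(retained, "cutoff_km")),
    class = "hull_result")
}

#' @export
print.hull_result <- function(x, ...) {
  cat(sprintf("Service area, base %s (%s): %d/%d missions retained, %.0f km2, median distance %.1f km (IQR %.1f)\n",
              x$base_id, x$period, x$n_retained, x$n_input, x$area_km2,
              x$median_distance_km, x$iqr_distance_km))
  invisible(x)
}

#' Compare a base's service area across periods
#'
#' Absolute and percent change in hull area, and the post-minus-pre
#' difference in median mission distance with a Mann-Whitney p-value and a
#' Hodges-Lehmann 95% confidence interval.
#'
#' @param pre,post `hull_result` objects for the same base.
#' @param pre_distances,post_distances Optional distance vectors (km);
#'   default: those stored in the results.
#' @return One-row `data.frame`.
#' @export
compare_periods <- function(pre, post, pre_distances = pre$distances_km,
                            post_distances = post$distances_km) {
  if (!identical(pre$base_id, post$base_id))
    stop("pre and post results are for different bases", call. = FALSE)
  hl <- hodges_lehmann_ci(post_distances, pre_distances)
  mw <- mann_whitney(post_distances, pre_distances)
  data.frame(
    base_id = pre$base_id,
    area_pre_km2 = pre$area_km2, area_post_km2 = post$area_km2,
    area_change_km2 = post$area_km2 - pre$area_km2,
    area_change_pct = 100 * (post$area_km2 - pre$area_km2) / pre$area_km2,
    median_pre_km = pre$median_distance_km,
    median_post_km = post$median_distance_km,
    median_diff_km = post$median_distance_km - pre$median_distance_km,
    hl_estimate_km = hl$estimate, hl_ci_low = hl$ci[1], hl_ci_high = hl$ci[2],
    mw_p = mw$p_value, stringsAsFactors = FALSE)
}

#' Full service-area analysis over bases and periods
#'
#' Restricts to map-eligible missions (GPS present), splits by base and
#' period, computes per-cell [hull_result()]s and per-base period
#' comparisons.
#'
#' @param missions Included mission table with `base_id`, `period`,
#'   `latitude`, `longitude`.
#' @param bases List of [base_definition()]s.
#' @param quantile Distance-filter quantile.
#' @return List with `hulls` (named list of `hull_result`) and `comparison`
#'   (`data.frame`, one row per base).
#' @export
service_areas <- function(missions, bases, quantile = 0.95) {
  m <- missions[!is.na(missions$latitude) & !is.na(missions$longitude), ]
  hulls <- list(); rows <- list()
  for (base in bases) {
    res <- list()
    for (per in c("pre", "post")) {
      pts <- m[m$base_id == base$base_id & m$period == per,
               c("latitude", "longitude"), drop = FALSE]
      if (nrow(pts) == 0L) next
      res[[per]] <- hull_result(pts, base, per, quantile)
      hulls[[paste(base$base_id, per, sep = "_")]] <- res[[per]]
    }
    if (!is.null(res$pre) && !is.null(res$post))
      rows[[base$base_id]] <- compare_periods(res$pre, res$post)
  }
  list(hulls = hulls, comparison = do.call(rbind, c(rows,
                                                    make.row.names = FALSE)))
}

#' Write service-area hulls as GeoJSON
#'
#' One Polygon feature per base/period with `base_id`, `period` and
#' `area_km2` properties; coordinates are `[longitude, latitude]` closed
#' rings per the GeoJSON convention.
#'
#' @param hulls Named list of `hull_result`s (see [service_areas()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hulls_geojson <- function(hulls, path) {
  feats <- lapply(hulls, function(h) {
    ring <- h$hull_vertices
    coords <- cbind(ring$longitude, ring$latitude)
    coords <- rbind(coords, coords[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(base_id = h$base_id, period = h$period,
                           area_km2 = h$area_km2),
         geometry = list(type = "Polygon",
                         coordinates = list(coords)))
  })
  names(feats) <- NULL
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
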