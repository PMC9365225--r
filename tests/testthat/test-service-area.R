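test_that("geodesic distance is zero at identity and symmetric", {
  expect_equal(geodesic_distance(63.4, 10.9, 63.4, 10.9), 0)
  set.seed(1)
  a_lat <- runif(200, 55, 70); a_lon <- runif(200, -5, 25)
  b_lat <- runif(200, 55, 70); b_lon <- runif(200, -5, 25)
  expect_equal(geodesic_distance(a_lat, a_lon, b_lat, b_lon),
               geodesic_distance(b_lat, b_lon, a_lat, a_lon))
  expect_error(geodesic_distance(91, 0, 0, 0), "latitude")
})

test_that("one meridian degree at the equator matches the WGS84 arc length", {
  # oracle: numerically integrated meridian radius of curvature
  a <- 6378137; f <- 1 / 298.257223563; e2 <- f * (2 - f)
  arc <- integrate(function(phi) a * (1 - e2) / (1 - e2 * sin(phi)^2)^1.5,
                   0, pi / 180, rel.tol = 1e-12)$value / 1000
  expect_equal(geodesic_distance(0, 0, 1, 0), arc, tolerance = 0.01 / arc)
  expect_lt(abs(geodesic_distance(0, 0, 1, 0) - 110.574), 0.01)
})

test_that("distance filter removes exactly the farthest 5% and is idempotent", {
  base <- one_base()[[1]]
  set.seed(2)
  pts <- sample_location(base, 150, 100)
  d <- geodesic_distance(pts$latitude, pts$longitude,
                         base$latitude, base$longitude)
  expect_equal(length(unique(d)), 100L)   # distinct distances
  kept <- filter_distance_outliers(pts, base, 0.95)
  expect_equal(nrow(kept), 95L)
  # brute-force sort-and-cut oracle
  oracle_keep <- pts[order(d)[1:95], ]
  expect_setequal(paste(kept$latitude, kept$longitude),
                  paste(oracle_keep$latitude, oracle_keep$longitude))
  # repeated filtering only ever shrinks, by at most the quantile fraction,
  # and never reorders: the pass-2 set is a subset of pass-1
  again <- filter_distance_outliers(kept, base, 0.95)
  expect_lte(nrow(kept) - nrow(again), ceiling(0.05 * nrow(kept)))
  expect_true(all(paste(again$latitude, again$longitude) %in%
                    paste(kept$latitude, kept$longitude)))
  same <- filter_distance_outliers(kept, base, 1)
  expect_equal(nrow(same), 95L)
  expect_error(filter_distance_outliers(pts[0, ], base), "non-empty")
})

test_that("identical points are never filtered", {
  base <- one_base()[[1]]
  pts <- data.frame(latitude = rep(63.6, 10), longitude = rep(11, 10))
  expect_equal(nrow(filter_distance_outliers(pts, base)), 10L)
})

test_that("hull of planted corners plus interior points is the corners", {
  corners <- data.frame(latitude = c(63, 63, 64, 64),
                        longitude = c(10, 12, 12, 10))
  set.seed(3)
  interior <- data.frame(latitude = runif(10, 63.2, 63.8),
                         longitude = runif(10, 10.3, 11.7))
  ring <- convex_hull(rbind(corners, interior))
  expect_equal(nrow(ring), 4L)
  expect_setequal(paste(ring$latitude, ring$longitude),
                  paste(corners$latitude, corners$longitude))
  # three points give the triangle through all three
  tri <- convex_hull(corners[1:3, ])
  expect_equal(nrow(tri), 3L)
})

test_that("degenerate inputs give zero-area flagged rings", {
  two <- convex_hull(data.frame(latitude = c(63, 64), longitude = c(10, 10)))
  expect_true(isTRUE(attr(two, "degenerate")))
  expect_equal(hull_area_km2(two), 0)
  col <- convex_hull(data.frame(latitude = c(63, 63.5, 64),
                                longitude = c(10, 10, 10)))
  expect_equal(hull_area_km2(col), 0, tolerance = 1e-6)
})

test_that("hull vertices agree with the cubic edge-test oracle", {
  set.seed(4)
  for (rep in 1:10) {
    pts <- data.frame(latitude = runif(50, 63, 63.2),
                      longitude = runif(50, 10, 10.4))
    ring <- convex_hull(pts)
    oracle <- hull_oracle_vertices(pts)
    expect_setequal(paste(ring$latitude, ring$longitude),
                    paste(pts$latitude[oracle], pts$longitude[oracle]))
  }
})

test_that("every retained point lies inside or on the hull", {
  base <- one_base()[[1]]
  set.seed(5)
  pts <- sample_location(base, 120, 300)
  kept <- filter_distance_outliers(pts, base)
  ring <- convex_hull(kept, center = c(base$latitude, base$longitude))
  expect_true(all(points_in_hull(kept, ring)))
})

test_that("hull area is monotone under subsetting and filtering", {
  base <- one_base()[[1]]
  set.seed(6)
  for (rep in 1:10) {
    pts <- sample_location(base, 150, 60)
    full <- hull_area_km2(convex_hull(pts))
    sub <- pts[sample(60, 30), ]
    expect_lte(hull_area_km2(convex_hull(sub)), full + 1e-9)
    filt <- filter_distance_outliers(pts, base)
    expect_lte(hull_area_km2(convex_hull(filt)), full + 1e-9)
  }
})

test_that("small equatorial square area matches the planar arc product", {
  sq <- data.frame(latitude = c(0, 0, 0.1, 0.1),
                   longitude = c(0, 0.1, 0.1, 0))
  a <- 6378137; f <- 1 / 298.257223563; e2 <- f * (2 - f)
  mer <- integrate(function(phi) a * (1 - e2) / (1 - e2 * sin(phi)^2)^1.5,
                   0, 0.1 * pi / 180, rel.tol = 1e-12)$value / 1000
  par_arc <- a * 0.1 * pi / 180 / 1000   # parallel arc at the equator
  planar <- mer * par_arc
  expect_lt(abs(hull_area_km2(sq) - planar) / planar, 0.005)
})

test_that("ring area is invariant to the starting vertex and cross-checked", {
  base <- one_base()[[1]]
  set.seed(7)
  ring <- convex_hull(sample_location(base, 200, 40))
  a1 <- hull_area_km2(ring)
  rot <- ring[c(3:nrow(ring), 1:2), ]
  expect_lt(abs(hull_area_km2(rot) - a1) / a1, 0.001)
  # independent ellipsoidal-area oracle
  ref <- geosphere::areaPolygon(cbind(ring$longitude, ring$latitude)) / 1e6
  expect_lt(abs(a1 - ref) / ref, 0.002)
  # self-intersecting bowtie is refused
  bow <- data.frame(latitude = c(63, 64, 63, 64),
                    longitude = c(10, 12, 12, 10))
  expect_error(hull_area_km2(bow), "self-intersecting")
})

test_that("period comparison reproduces direct percent-change arithmetic", {
  base <- one_base()[[1]]
  set.seed(8)
  pre <- hull_result(sample_location(base, 150, 400), base, "pre")
  post <- hull_result(sample_location(base, 100, 200), base, "post")
  cmp <- compare_periods(pre, post)
  expect_equal(cmp$area_change_pct,
               100 * (post$area_km2 - pre$area_km2) / pre$area_km2)
  expect_equal(cmp$median_diff_km,
               median(post$distances_km) - median(pre$distances_km))
  expect_true(cmp$mw_p >= 0 && cmp$mw_p <= 1)
  expect_lte(cmp$hl_ci_low, cmp$hl_estimate_km)
  expect_gte(cmp$hl_ci_high, cmp$hl_estimate_km)
  # identical point sets: zero change
  same <- compare_periods(pre, pre)
  expect_equal(same$area_change_km2, 0)
  expect_equal(same$area_change_pct, 0)
  # mismatched bases are refused
  other <- post; other$base_id <- "zz"
  expect_error(compare_periods(pre, other), "different bases")
})

test_that("hulls serialise to valid closed GeoJSON polygons", {
  base <- one_base()[[1]]
  set.seed(9)
  hr <- hull_result(sample_location(base, 150, 100), base, "pre")
  path <- withr::local_tempfile(fileext = ".geojson")
  write_hulls_geojson(list(alpha_pre = hr), path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  expect_identical(ring[[1]], ring[[length(ring)]])   # closed
  expect_equal(gj$features[[1]]$properties$area_km2, hr$area_km2)
  expect_equal(length(ring) - 1L, nrow(hr$hull_vertices))
})
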