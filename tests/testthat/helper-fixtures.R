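# small, fast configurations and hand-built series used across test files

one_base <- function() list(base_definition("alpha", 63.5, 10.9, 3))

tiny_config <- function(seed = 1L, ...) {
  sim_config(bases = one_base(), missions_per_month = 40,
             months_pre = 12L, months_post = 6L,
             exclusion_rates = c(cancelled = 0, car = 0, sar = 0,
                                 secondary = 0, not_acute = 0,
                                 no_contact = 0, missing_gps = 0),
             seed = seed, ...)
}

# monthly series straight from the segmented mean function + MA(1) shocks,
# bypassing mission-level generation (for ITS-focused tests)
make_series <- function(beta = c(30, 0.05, 0, 0, 1.1), theta = 0, sd = 1,
                        months_pre = 24L, months_post = 12L,
                        study_start = "2017-01") {
  n <- months_pre + months_post
  months <- month_seq_public(study_start, n)
  t <- seq_len(n) - 1L
  step <- as.numeric(t >= months_pre)
  ramp <- (t - months_pre) * step
  w <- as.numeric(is_winter(months))
  mu <- beta[1] + beta[2] * t + beta[3] * step + beta[4] * ramp + beta[5] * w
  y <- mu + simulate_ma1_shocks(n, theta, sd)
  s <- data.frame(month = months, t = t, n_missions = 50L,
                  mean_response = y, included = TRUE,
                  exclusion_reason = "none", stringsAsFactors = FALSE)
  class(s) <- c("monthly_series", "data.frame")
  s
}

# month sequence without reaching into internals
month_seq_public <- function(start, n) {
  y0 <- as.integer(substr(start, 1, 4)); m0 <- as.integer(substr(start, 6, 7))
  k <- (y0 * 12L + m0 - 1L) + seq_len(n) - 1L
  sprintf("%04d-%02d", k %/% 12L, k %% 12L + 1L)
}

# a minimal mission table built by hand
mk_missions <- function(n, base_id = "alpha",
                        alarm = as.POSIXct("2018-05-10 12:00:00", tz = "UTC"),
                        response_min = 30, takeoff_min = 5,
                        mission_type = "primary", urgency = "acute",
                        completed = TRUE, patient_contact = TRUE,
                        latitude = 63.5, longitude = 10.9,
                        period = "pre") {
  if (n == 0L) return(mk_missions(1)[0, , drop = FALSE])
  alarm <- rep(alarm, length.out = n) + (seq_len(n) - 1) * 3600
  data.frame(mission_id = sprintf("T%04d", seq_len(n)), base_id = base_id,
             month = format(alarm, "%Y-%m"), period = period,
             alarm_time = alarm,
             takeoff_time = alarm + rep(takeoff_min, length.out = n) * 60,
             on_scene_time = alarm + rep(response_min, length.out = n) * 60,
             urgency = urgency, mission_type = mission_type,
             completed = completed, patient_contact = patient_contact,
             latitude = latitude, longitude = longitude,
             response_min = rep(response_min, length.out = n),
             stringsAsFactors = FALSE)
}

# O(n^3) convex-hull oracle: a point is a hull vertex iff it lies on an
# edge (i,j) with every other point on one side. The oracle projects into
# the same azimuthal plane as the implementation (hull vertex membership of
# near-collinear points is projection-dependent) but does so with its own
# geosphere calls, and uses exhaustive edge testing instead of a scan.
hull_oracle_vertices <- function(pts) {
  inv <- geosphere::geodesic_inverse(
    cbind(mean(pts$longitude), mean(pts$latitude)),
    cbind(pts$longitude, pts$latitude))
  az <- inv[, "azimuth1"] * pi / 180
  x <- inv[, "distance"] * sin(az)
  y <- inv[, "distance"] * cos(az)
  n <- length(x)
  on_hull <- rep(FALSE, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cr <- (x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i])
    cr[c(i, j)] <- 0
    if (all(cr <= 1e-9) || all(cr >= -1e-9)) on_hull[c(i, j)] <- TRUE
  }
  which(on_hull)
}
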