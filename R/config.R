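#' Define a HEMS base
#'
#' A helicopter base is described by its identifier, its WGS84 position and
#' the rotor start-up time of the airframe stationed there. The start-up time
#' is the physical lower bound on the alarm-to-takeoff interval for a crew
#' alarmed on the ground, and therefore also a lower bound on any response
#' time generated for that base.
#'
#' @param base_id Character label, e.g. `"trondheim"`.
#' @param latitude,longitude WGS84 decimal degrees.
#' @param startup_time Rotor start-up time in minutes, `>= 0`.
#' @return A `base_definition` object (named list).
#' @export
base_definition <- function(base_id, latitude, longitude, startup_time) {
  if (!is.character(base_id) || length(base_id) != 1L || !nzchar(base_id))
    stop("base_id must be a non-empty character scalar", call. = FALSE)
  if (!is.numeric(latitude) || latitude < -90 || latitude > 90)
    stop("latitude must be in [-90, 90]", call. = FALSE)
  if (!is.numeric(longitude) || longitude < -180 || longitude > 180)
    stop("longitude must be in [-180, 180]", call. = FALSE)
  if (!is.numeric(startup_time) || startup_time < 0)
    stop("startup_time must be >= 0", call. = FALSE)
  structure(
    list(base_id = base_id, latitude = as.numeric(latitude),
         longitude = as.numeric(longitude),
         startup_time = as.numeric(startup_time)),
    class = "base_definition")
}

#' Simulation configuration for the synthetic mission generator
#'
#' Collects every parameter of the synthetic HEMS mission generator: the
#' study window, the bases, the deterministic monthly mean-response-time
#' function (baseline, pre-intervention slope, level and slope change at the
#' intervention, winter elevation), the MA(1) month-level error process,
#' mission-level noise, severity (NACA) distributions for the pre and post
#' periods, the in-flight-scramble probability and the spatial dispersion of
#' mission locations.
#'
#' The monthly mean response time at 0-based month index `t` is
#' `beta0 + beta1 * t + beta2 * u(t - tpi) + beta3 * (t - tpi) * u(t - tpi) +
#' beta4 * I_winter(t)`, where `tpi = months_pre` is the index of the
#' intervention month, `u` is the unit step (1 for arguments `>= 0`) and the
#' winter indicator is 1 for October through March. An MA(1) shock is added
#' at month level and i.i.d. normal noise at mission level, truncated below
#' so that no response time falls under the base's start-up time.
#'
#' @param study_start First study month as `"YYYY-MM"`.
#' @param months_pre Number of pre-intervention months (`> 0`); the
#'   intervention falls at 0-based month index `months_pre`.
#' @param months_post Number of months from the intervention month onwards
#'   (`>= 0`); the total study window is `months_pre + months_post` months.
#' @param bases List of [base_definition()] objects.
#' @param missions_per_month Expected eligible missions per base per month;
#'   a scalar (recycled) or one value per base.
#' @param beta0 Baseline mean response time (minutes) at `t = 0`.
#' @param beta1 Pre-intervention trend (minutes/month).
#' @param beta2 Level change at the intervention (minutes).
#' @param beta3 Slope change after the intervention (minutes/month).
#' @param beta4 Winter (Oct-Mar) elevation of the monthly mean (minutes).
#' @param ma_theta MA(1) coefficient of the month-level error, `|theta| < 1`.
#' @param month_shock_sd SD (minutes) of the MA(1) innovations.
#' @param mission_noise_sd SD (minutes) of mission-level noise.
#' @param naca_props_pre,naca_props_post Probability vectors of length 8 over
#'   NACA scores 0-7, each summing to 1.
#' @param scramble_prob Probability that a mission is an in-flight scramble
#'   (alarm-to-takeoff under 2 minutes).
#' @param max_mission_radius_km Maximum geodesic distance (km) of a mission
#'   location from its base.
#' @param intervention_day Day of month on which the coordinator starts
#'   within the intervention month (records from that instant on are "post").
#' @param prop_two_patients Probability that a mission carries two patients.
#' @param male_prop_pre,male_prop_post Proportion of male patients.
#' @param age_mean_pre,age_mean_post,age_sd Age distribution (years), normal
#'   clipped to `[0, 100]`.
#' @param icd10_props Named probability vector over ICD-10 chapter labels.
#' @param exclusion_rates Named vector of per-reason rates, each expressed
#'   relative to the eligible mission rate, for generating records that the
#'   inclusion filter should drop (`cancelled`, `car`, `sar`, `secondary`,
#'   `not_acute`, `no_contact`); `missing_gps` is the fraction of eligible
#'   missions with no usable GPS position.
#' @param seed Integer seed; identical configurations with identical seeds
#'   regenerate byte-identical datasets.
#' @return A validated `sim_config` object.
#' @seealso [default_config()] for defaults reproducing the published
#'   regional magnitudes, [generate_missions()].
#' @export
sim_config <- function(study_start = "2017-01",
                       months_pre = 24L,
                       months_post = 12L,
                       bases = default_bases(),
                       missions_per_month = c(46, 28, 13.5),
                       beta0 = 29.9, beta1 = 0.05,
                       beta2 = -0.13, beta3 = -0.13, beta4 = 1.1,
                       ma_theta = 0.3,
                       month_shock_sd = 1.5,
                       mission_noise_sd = 8,
                       naca_props_pre = c(0.005, 0.03, 0.10, 0.25,
                                          0.30, 0.20, 0.07, 0.045),
                       naca_props_post = c(0.004, 0.025, 0.079, 0.21,
                                           0.34, 0.22, 0.077, 0.045),
                       scramble_prob = 0.12,
                       max_mission_radius_km = 150,
                       intervention_day = 7L,
                       prop_two_patients = 0.017,
                       male_prop_pre = 0.635, male_prop_post = 0.66,
                       age_mean_pre = 54, age_mean_post = 58, age_sd = 24,
                       icd10_props = c(G = 0.040, I = 0.354, J = 0.057,
                                       M = 0.015, O = 0.023, R = 0.149,
                                       `S-T` = 0.295, other = 0.067),
                       exclusion_rates = c(cancelled = 0.10, car = 0.02,
                                           sar = 0.02, secondary = 0.05,
                                           not_acute = 0.04,
                                           no_contact = 0.02,
                                           missing_gps = 0.022),
                       seed = 1L) {
  cfg <- list(study_start = study_start, months_pre = as.integer(months_pre),
              months_post = as.integer(months_post), bases = bases,
              missions_per_month = missions_per_month,
              beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
              beta4 = beta4, ma_theta = ma_theta,
              month_shock_sd = month_shock_sd,
              mission_noise_sd = mission_noise_sd,
              naca_props_pre = naca_props_pre,
              naca_props_post = naca_props_post,
              scramble_prob = scramble_prob,
              max_mission_radius_km = max_mission_radius_km,
              intervention_day = as.integer(intervention_day),
              prop_two_patients = prop_two_patients,
              male_prop_pre = male_prop_pre, male_prop_post = male_prop_post,
              age_mean_pre = age_mean_pre, age_mean_post = age_mean_post,
              age_sd = age_sd, icd10_props = icd10_props,
              exclusion_rates = exclusion_rates, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Default base set
#'
#' Three bases in Mid-Norway with approximate coordinates: a university
#' hospital base (start-up 3 min), a coastal base (start-up 2 min) and a
#' military search-and-rescue base that also flies ambulance missions
#' (start-up 10 min).
#'
#' @return List of three [base_definition()] objects.
#' @export
default_bases <- function() {
  list(base_definition("trondheim", 63.458, 10.926, 3),
       base_definition("alesund",   62.561,  6.110, 2),
       base_definition("orland",    63.699,  9.604, 10))
}

#' Default simulation configuration
#'
#' [sim_config()] evaluated at its defaults: a 36-month window (24 pre, 12
#' post) starting January 2017, intervention on day 7 of month index 24,
#' roughly 87 eligible regional missions per month across three bases,
#' baseline monthly mean response near 31 minutes with a 1.1-minute winter
#' elevation, MA(1) month-level autocorrelation (theta 0.3), severe-case
#' (NACA 4-7) proportions 0.615 pre / 0.682 post, and a 12% in-flight
#' scramble probability.
#'
#' @param seed Integer seed.
#' @return A `sim_config` object.
#' @export
default_config <- function(seed = 1L) sim_config(seed = seed)

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fail <- function(field, msg)
    stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
  if (!grepl("^\\d{4}-\\d{2}$", cfg$study_start))
    fail("study_start", "must be 'YYYY-MM'")
  if (cfg$months_pre <= 0L) fail("months_pre", "must be > 0")
  if (cfg$months_post < 0L) fail("months_post", "must be >= 0")
  if (length(cfg$bases) < 1L ||
      !all(vapply(cfg$bases, inherits, logical(1), "base_definition")))
    fail("bases", "must be a non-empty list of base_definition objects")
  nb <- length(cfg$bases)
  if (!length(cfg$missions_per_month) %in% c(1L, nb) ||
      any(cfg$missions_per_month <= 0))
    fail("missions_per_month", "must be positive, length 1 or one per base")
  for (f in c("beta0", "beta1", "beta2", "beta3", "beta4"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]))
      fail(f, "must be a finite number")
  if (abs(cfg$ma_theta) >= 1) fail("ma_theta", "must satisfy |theta| < 1")
  if (cfg$month_shock_sd < 0) fail("month_shock_sd", "must be >= 0")
  if (cfg$mission_noise_sd < 0) fail("mission_noise_sd", "must be >= 0")
  for (f in c("naca_props_pre", "naca_props_post")) {
    p <- cfg[[f]]
    if (length(p) != 8L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      fail(f, "must be 8 non-negative probabilities summing to 1 (1e-9)")
  }
  if (cfg$scramble_prob < 0 || cfg$scramble_prob > 1)
    fail("scramble_prob", "must be in [0, 1]")
  if (cfg$max_mission_radius_km <= 0)
    fail("max_mission_radius_km", "must be > 0")
  if (cfg$intervention_day < 1L || cfg$intervention_day > 28L)
    fail("intervention_day", "must be in 1..28")
  if (abs(sum(cfg$icd10_props) - 1) > 1e-9 || any(cfg$icd10_props < 0))
    fail("icd10_props", "must be non-negative and sum to 1 (1e-9)")
  if (any(cfg$exclusion_rates < 0))
    fail("exclusion_rates", "must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("HEMS mission simulation configuration\n")
  cat(sprintf("  window: %s + %d pre / %d post months, %d bases\n",
              x$study_start, x$months_pre, x$months_post, length(x$bases)))
  cat(sprintf("  mean function: beta0=%.3g beta1=%.3g beta2=%.3g beta3=%.3g beta4=%.3g\n",
              x$beta0, x$beta1, x$beta2, x$beta3, x$beta4))
  cat(sprintf("  errors: MA(1) theta=%.3g, month shock SD=%.3g, mission SD=%.3g\n",
              x$ma_theta, x$month_shock_sd, x$mission_noise_sd))
  cat(sprintf("  scramble prob=%.3g, seed=%d\n", x$scramble_prob, x$seed))
  invisible(x)
}

#' Read / write a simulation configuration file
#'
#' The configuration is stored as a flat YAML key-value file; bases are
#' encoded as a list of `base_id`/`latitude`/`longitude`/`startup_time`
#' blocks. Every field has a documented default ([sim_config()]), so a
#' partial file is completed with defaults.
#'
#' @param path File path.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$bases))
    raw$bases <- lapply(raw$bases, function(b)
      base_definition(b$base_id, b$latitude, b$longitude, b$startup_time))
  for (f in c("naca_props_pre", "naca_props_post", "missions_per_month",
              "icd10_props", "exclusion_rates"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A `sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  out$bases <- lapply(out$bases, unclass)
  # named vectors must be written as maps, not bare sequences
  for (f in c("icd10_props", "exclusion_rates"))
    out[[f]] <- as.list(out[[f]])
  yaml::write_yaml(out, path)
  invisible(path)
}

# ---- month arithmetic helpers (YYYY-MM strings, 0-based indices) ----

month_to_int <- function(ym) {
  y <- as.integer(substr(ym, 1, 4)); m <- as.integer(substr(ym, 6, 7))
  y * 12L + (m - 1L)
}

int_to_month <- function(k) {
  sprintf("%04d-%02d", k %/% 12L, k %% 12L + 1L)
}

#' Sequence of study months
#' @param study_start `"YYYY-MM"`.
#' @param n_months Number of months.
#' @return Character vector of `"YYYY-MM"` labels.
#' @keywords internal
month_seq <- function(study_start, n_months) {
  int_to_month(month_to_int(study_start) + seq_len(n_months) - 1L)
}

month_index <- function(ym, study_start) {
  month_to_int(ym) - month_to_int(study_start)
}

month_start_posix <- function(ym) {
  as.POSIXct(paste0(ym, "-01 00:00:00"), tz = "UTC")
}

#' Winter indicator
#'
#' TRUE for calendar months October through March, the season in which
#' monthly mean response times are elevated.
#'
#' @param ym `"YYYY-MM"` month labels.
#' @return Logical vector.
#' @export
is_winter <- function(ym) {
  m <- as.integer(substr(ym, 6, 7))
  m >= 10L | m <= 3L
}

#' Intervention date implied by a configuration
#' @param config A `sim_config`.
#' @return POSIXct (UTC) of the coordinator start.
#' @export
intervention_date <- function(config) {
  ym <- int_to_month(month_to_int(config$study_start) + config$months_pre)
  as.POSIXct(sprintf("%s-%02d 00:00:00", ym, config$intervention_day),
             tz = "UTC")
}
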