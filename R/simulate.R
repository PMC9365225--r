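#' Simulate an MA(1) month-level shock series
#'
#' Generates `e_t = z_t + theta * z_(t-1)` with `z_t` i.i.d. normal with mean
#' 0 and standard deviation `sd`. This is the month-level error process of
#' the monthly mean response time: adjacent months are correlated with lag-1
#' autocorrelation `theta / (1 + theta^2)`, and correlation vanishes beyond
#' lag 1.
#'
#' @param n_months Number of months, `>= 1`.
#' @param theta MA(1) coefficient, `|theta| < 1`.
#' @param sd Innovation SD in minutes, `>= 0`.
#' @return Numeric vector of length `n_months`.
#' @export
simulate_ma1_shocks <- function(n_months, theta, sd) {
  if (abs(theta) >= 1) stop("|theta| must be < 1", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (n_months < 1L) stop("n_months must be >= 1", call. = FALSE)
  z <- stats::rnorm(n_months + 1L, 0, sd)
  z[-1L] + theta * z[-(n_months + 1L)]
}

#' Sample mission locations around a base
#'
#' Draws points approximately area-uniformly over the geodesic disc of
#' radius `max_radius_km` centred on the base: uniform bearing, distance
#' `max_radius_km * sqrt(U)` (density increasing linearly with distance), and
#' the WGS84 direct geodesic problem to place the point. Every returned
#' point lies within `max_radius_km` of the base.
#'
#' @param base A [base_definition()].
#' @param max_radius_km Positive radius in km.
#' @param n Number of points.
#' @return `data.frame` with columns `latitude`, `longitude`.
#' @export
sample_location <- function(base, max_radius_km, n = 1L) {
  if (max_radius_km <= 0) stop("max_radius_km must be > 0", call. = FALSE)
  if (n == 0L)
    return(data.frame(latitude = numeric(0), longitude = numeric(0)))
  bearing <- stats::runif(n, 0, 360)
  d_km <- max_radius_km * sqrt(stats::runif(n))
  p <- geosphere::geodesic(cbind(base$longitude, base$latitude),
                           azi = bearing, d = d_km * 1000)
  data.frame(latitude = p[, "latitude"], longitude = p[, "longitude"])
}

# truncated-normal draw; lower may be a vector. sd == 0 degenerates to the
# (truncated) mean so noiseless configurations reproduce the mean function
# exactly.
rtrunc_norm <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(pmax(rep_len(mean, n), lower))
  plo <- stats::pnorm(lower, mean = mean, sd = sd)
  u <- stats::runif(n, plo, 1)
  stats::qnorm(pmin(u, 1 - 1e-16), mean = mean, sd = sd)
}

#' Deterministic monthly mean-response function of a configuration
#'
#' The segmented mean `beta0 + beta1*t + beta2*u(t - tpi) +
#' beta3*(t - tpi)*u(t - tpi) + beta4*I_winter(t)` evaluated over the whole
#' study window (no error terms), with `tpi = months_pre`.
#'
#' @param config A `sim_config`.
#' @return `data.frame` with `month`, `t`, `winter`, `mu` (minutes).
#' @export
monthly_mean_function <- function(config) {
  n <- config$months_pre + config$months_post
  months <- month_seq(config$study_start, n)
  t <- seq_len(n) - 1L
  tpi <- config$months_pre
  step <- as.numeric(t >= tpi)
  ramp <- (t - tpi) * step
  w <- as.numeric(is_winter(months))
  mu <- config$beta0 + config$beta1 * t + config$beta2 * step +
    config$beta3 * ramp + config$beta4 * w
  data.frame(month = months, t = t, winter = w, mu = mu)
}

#' Generate a synthetic HEMS mission dataset
#'
#' Produces one row per mission over the configured study window. Monthly
#' mean response times follow the segmented intervention model of
#' [monthly_mean_function()] plus a shared regional MA(1) month shock;
#' individual missions add i.i.d. normal noise truncated below at the base's
#' start-up time (or at the drawn alarm-to-takeoff interval when that is
#' longer, so timeline ordering always holds). A mission is an in-flight
#' scramble with probability `scramble_prob`, in which case its
#' alarm-to-takeoff interval is drawn uniformly on `[0, 2)` minutes;
#' otherwise the interval is uniform on `[startup, startup + 10]` minutes.
#' NACA severity scores are drawn from the period-appropriate probability
#' vector. Records destined for exclusion (cancelled, rapid-response car,
#' search-and-rescue, secondary, non-acute, no patient contact) are generated
#' at the configured rates so the inclusion filter is exercised; a fraction
#' of missions lack GPS positions.
#'
#' The same configuration and seed always regenerate an identical dataset.
#'
#' @param config A `sim_config`.
#' @return An object of class `hems_sim`: a list with
#'   \describe{
#'     \item{missions}{mission table (one row per mission) with timeline
#'       columns (`alarm_time`, `takeoff_time`, `on_scene_time`, POSIXct
#'       UTC), categorical fields, WGS84 coordinates, the full-precision
#'       generated `response_min`, and generator ground-truth columns
#'       `scramble`, `eligible`, `excl_reason`;}
#'     \item{patients}{per-patient sidecar keyed by `mission_id` with `age`,
#'       `sex`, `naca`, `icd10_chapter`, `contact_time`;}
#'     \item{monthly_truth}{the deterministic mean function plus the
#'       realised MA(1) shock per month;}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_missions <- function(config) {
  validate_config(config)
  cfg <- config
  n_months <- cfg$months_pre + cfg$months_post
  mf <- monthly_mean_function(cfg)
  rates <- rep_len(cfg$missions_per_month, length(cfg$bases))
  iv_date <- intervention_date(cfg)

  set.seed(cfg$seed)
  shocks <- simulate_ma1_shocks(n_months, cfg$ma_theta, cfg$month_shock_sd)
  mu_month <- mf$mu + shocks

  excl_reasons <- c("cancelled", "car", "sar", "secondary", "not_acute",
                    "no_contact")
  er <- cfg$exclusion_rates
  mission_rows <- list()
  patient_rows <- list()

  for (bi in seq_along(cfg$bases)) {
    base <- cfg$bases[[bi]]
    set.seed(cfg$seed + bi)
    # per-month counts: eligible plus one Poisson count per exclusion reason
    n_elig <- stats::rpois(n_months, rates[bi])
    n_excl <- vapply(excl_reasons, function(r)
      stats::rpois(n_months, rates[bi] * er[[r]]), numeric(n_months))
    if (n_months == 1L) n_excl <- matrix(n_excl, nrow = 1L)

    month_of <- rep.int(seq_len(n_months), n_elig)
    reason_of <- rep("none", length(month_of))
    for (r in seq_along(excl_reasons)) {
      month_of <- c(month_of, rep.int(seq_len(n_months), n_excl[, r]))
      reason_of <- c(reason_of,
                     rep(excl_reasons[r], sum(n_excl[, r])))
    }
    nm <- length(month_of)
    if (nm == 0L) next

    month_lab <- mf$month[month_of]
    m_start <- month_start_posix(month_lab)
    m_len <- as.numeric(month_start_posix(int_to_month(
      month_to_int(month_lab) + 1L))) - as.numeric(m_start)
    alarm <- m_start + floor(stats::runif(nm) * m_len)

    scramble <- stats::runif(nm) < cfg$scramble_prob
    interval <- ifelse(scramble, stats::runif(nm, 0, 2),
                       base$startup_time + stats::runif(nm, 0, 10))
    lower <- pmax(base$startup_time, interval + 0.1)
    response <- rtrunc_norm(nm, mu_month[month_of], cfg$mission_noise_sd,
                            lower)
    loc <- sample_location(base, cfg$max_mission_radius_km, nm)
    gps_missing <- stats::runif(nm) < er[["missing_gps"]]
    loc$latitude[gps_missing] <- NA_real_
    loc$longitude[gps_missing] <- NA_real_

    urgency <- ifelse(reason_of == "not_acute", "other", "acute")
    mtype <- rep("primary", nm)
    mtype[reason_of == "car"] <- "car"
    mtype[reason_of == "sar"] <- "sar"
    mtype[reason_of == "secondary"] <- "secondary"
    completed <- reason_of != "cancelled"
    contact <- !(reason_of %in% c("cancelled", "no_contact"))

    takeoff <- alarm + floor(interval * 60)
    on_scene <- alarm + ceiling(response * 60)
    on_scene[!completed] <- NA
    response[!completed] <- NA_real_

    df <- data.frame(
      base_id = base$base_id, month = month_lab,
      alarm_time = alarm, takeoff_time = takeoff, on_scene_time = on_scene,
      urgency = urgency, mission_type = mtype, completed = completed,
      patient_contact = contact,
      latitude = loc$latitude, longitude = loc$longitude,
      response_min = response, scramble = scramble,
      eligible = reason_of == "none", excl_reason = reason_of,
      stringsAsFactors = FALSE)

    # patients for every mission with patient contact
    has_pat <- which(contact)
    n_pat <- 1L + stats::rbinom(length(has_pat), 1L, cfg$prop_two_patients)
    pidx <- rep.int(has_pat, n_pat)
    pno <- sequence(n_pat)
    npat <- length(pidx)
    post <- alarm[pidx] >= iv_date
    naca <- ifelse(post,
                   sample(0:7, npat, TRUE, cfg$naca_props_post),
                   sample(0:7, npat, TRUE, cfg$naca_props_pre))
    # two independent streams above would desynchronise RNG use; draw both
    # and select, so the draw count is fixed regardless of period mix
    sex <- ifelse(stats::runif(npat) <
                    ifelse(post, cfg$male_prop_post, cfg$male_prop_pre),
                  "male", "female")
    age <- round(pmin(100, pmax(0, stats::rnorm(
      npat, ifelse(post, cfg$age_mean_post, cfg$age_mean_pre), cfg$age_sd))))
    icd <- sample(names(cfg$icd10_props), npat, TRUE, cfg$icd10_props)
    contact_time <- on_scene[pidx]
    extra <- pno > 1L
    contact_time[extra] <- contact_time[extra] +
      round(stats::runif(sum(extra), 60, 600))

    pdf <- data.frame(
      base_row = pidx + 0, patient_no = pno, age = age, sex = sex,
      naca = naca, icd10_chapter = icd, contact_time = contact_time,
      stringsAsFactors = FALSE)
    pdf$base_id <- base$base_id
    mission_rows[[bi]] <- df
    patient_rows[[bi]] <- pdf
  }

  missions <- do.call(rbind, mission_rows)
  # stable ordering and ids: chronological, ties broken by base then row
  ord <- order(missions$alarm_time, missions$base_id)
  # map original (base, row) to final id for the patient sidecar
  key <- paste(missions$base_id,
               unlist(lapply(mission_rows, function(d) seq_len(nrow(d)))))
  missions <- missions[ord, , drop = FALSE]
  rownames(missions) <- NULL
  missions$mission_id <- sprintf("M%05d", seq_len(nrow(missions)))
  id_of <- stats::setNames(missions$mission_id, key[ord])

  patients <- do.call(rbind, patient_rows)
  if (!is.null(patients) && nrow(patients) > 0) {
    patients$mission_id <- id_of[paste(patients$base_id, patients$base_row)]
    patients <- patients[order(patients$mission_id, patients$patient_no),
                         c("mission_id", "patient_no", "age", "sex", "naca",
                           "icd10_chapter", "contact_time")]
    rownames(patients) <- NULL
  }

  missions$period <- ifelse(missions$alarm_time >= iv_date, "post", "pre")
  first <- c("mission_id", "base_id", "month", "period")
  missions <- missions[, c(first, setdiff(names(missions), first))]

  structure(list(missions = missions, patients = patients,
                 monthly_truth = cbind(mf, shock = shocks,
                                       mu_realised = mu_month),
                 config = cfg),
            class = "hems_sim")
}

#' @export
print.hems_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic HEMS dataset: %d missions (%d eligible), %d patients, %d months, seed %d\n",
    nrow(x$missions), sum(x$missions$eligible),
    if (is.null(x$patients)) 0L else nrow(x$patients),
    x$config$months_pre + x$config$months_post, x$config$seed))
  invisible(x)
}
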