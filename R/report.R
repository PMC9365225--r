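#' In-flight scramble rates by base and period
#'
#' Classifies every mission with [is_inflight_scramble()] and tabulates the
#' scramble fraction per base and for the region, split by period, with a
#' chi-square p-value per row.
#'
#' @param missions Included mission table.
#' @return `data.frame` with one row per base plus `"all"`.
#' @export
scramble_rates <- function(missions) {
  sc <- is_inflight_scramble(missions)
  groups <- c("all", sort(unique(missions$base_id)))
  rows <- lapply(groups, function(g) {
    sel <- if (g == "all") rep(TRUE, nrow(missions))
           else missions$base_id == g
    pre <- sel & missions$period == "pre"
    post <- sel & missions$period == "post"
    if (!any(pre) || !any(post)) return(NULL)
    s_pre <- sum(sc & pre, na.rm = TRUE); s_post <- sum(sc & post, na.rm = TRUE)
    p <- tryCatch(chi_square_2xk(rbind(c(s_pre, sum(pre) - s_pre),
                                       c(s_post, sum(post) - s_post)))$p_value,
                  error = function(e) NA_real_)
    data.frame(base_id = g, n_pre = sum(pre), scrambles_pre = s_pre,
               pct_pre = 100 * s_pre / sum(pre),
               n_post = sum(post), scrambles_post = s_post,
               pct_post = 100 * s_post / sum(post),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Patient characteristics comparison table
#'
#' Pre/post comparison of patient age (median/IQR, Mann-Whitney), sex
#' (proportion male, chi-square), NACA severity (mean +/- SD, Welch t;
#' proportion NACA 4-7, chi-square) and the ICD-10 chapter distribution.
#'
#' @param patients Patient sidecar joined to included missions.
#' @param periods Character vector, the period of each patient's mission.
#' @return List with `summary` (`data.frame` of labelled rows) and `icd10`
#'   (chapter percentage table).
#' @export
patient_characteristics <- function(patients, periods) {
  stopifnot(nrow(patients) == length(periods))
  pre <- periods == "pre"; post <- periods == "post"
  age_mw <- mann_whitney(patients$age[post], patients$age[pre])
  male_tab <- rbind(table(factor(patients$sex[pre], c("male", "female"))),
                    table(factor(patients$sex[post], c("male", "female"))))
  naca_t <- t_test_means(patients$naca[post], patients$naca[pre])
  sev <- patients$naca >= 4
  sev_tab <- rbind(c(sum(sev[pre]), sum(!sev[pre])),
                   c(sum(sev[post]), sum(!sev[post])))
  summary <- data.frame(
    label = c("age median (IQR), years", "male, %", "NACA mean (SD)",
              "NACA 4-7, %"),
    pre = c(sprintf("%.1f (%.1f)", stats::median(patients$age[pre]),
                    stats::IQR(patients$age[pre])),
            sprintf("%.1f", 100 * mean(patients$sex[pre] == "male")),
            sprintf("%.2f (%.2f)", mean(patients$naca[pre]),
                    stats::sd(patients$naca[pre])),
            sprintf("%.1f", 100 * mean(sev[pre]))),
    post = c(sprintf("%.1f (%.1f)", stats::median(patients$age[post]),
                     stats::IQR(patients$age[post])),
             sprintf("%.1f", 100 * mean(patients$sex[post] == "male")),
             sprintf("%.2f (%.2f)", mean(patients$naca[post]),
                     stats::sd(patients$naca[post])),
             sprintf("%.1f", 100 * mean(sev[post]))),
    test = c("mann_whitney", "chi_square", "t_test", "chi_square"),
    p_value = c(age_mw$p_value, chi_square_2xk(male_tab)$p_value,
                naca_t$p_value, chi_square_2xk(sev_tab)$p_value),
    stringsAsFactors = FALSE)
  chapters <- sort(unique(patients$icd10_chapter))
  icd <- data.frame(
    chapter = chapters,
    pct_pre = vapply(chapters, function(ch)
      100 * mean(patients$icd10_chapter[pre] == ch), numeric(1)),
    pct_post = vapply(chapters, function(ch)
      100 * mean(patients$icd10_chapter[post] == ch), numeric(1)),
    stringsAsFactors = FALSE)
  list(summary = summary, icd10 = icd,
       severe_prop = c(pre = mean(sev[pre]), post = mean(sev[post])))
}

#' Mission distribution across bases
#'
#' Per-base mission counts and percentages by period, with an overall
#' chi-square test of distribution change.
#'
#' @param missions Included mission table.
#' @return List with `table` and `p_value`.
#' @export
mission_distribution <- function(missions) {
  tab <- table(missions$period, missions$base_id)
  tab <- tab[c("pre", "post"), , drop = FALSE]
  pct <- 100 * prop.table(tab, 1)
  p <- chi_square_2xk(unclass(tab))$p_value
  out <- data.frame(base_id = colnames(tab),
                    n_pre = as.integer(tab["pre", ]),
                    pct_pre = as.numeric(pct["pre", ]),
                    n_post = as.integer(tab["post", ]),
                    pct_post = as.numeric(pct["post", ]),
                    stringsAsFactors = FALSE)
  list(table = out, p_value = p)
}

#' Assemble the full evaluation report
#'
#' Collects every stage output — exclusion tally, monthly series, fitted
#' ITS model, service-area comparison, and the descriptive battery — into
#' machine-readable tables plus a plain-text summary. Every number in the
#' report is taken directly from a stage output; percentages are computed
#' from unrounded counts and rounded only at render time.
#'
#' @param included Included mission table.
#' @param patients Patient sidecar restricted to included missions.
#' @param tally `exclusion_tally` from [apply_inclusion_criteria()].
#' @param monthly Flagged `monthly_series`.
#' @param model Fitted `its_model`.
#' @param areas Output of [service_areas()].
#' @param threshold_min Response-time threshold (minutes).
#' @return Object of class `hems_report` (list of data frames + text lines).
#' @export
build_report <- function(included, patients, tally, monthly, model, areas,
                         threshold_min = 45) {
  for (nm in c("included", "patients", "tally", "monthly", "model", "areas"))
    if (is.null(get(nm)))
      stop(sprintf("missing stage output '%s'", nm), call. = FALSE)
  per_of <- included$period[match(patients$mission_id, included$mission_id)]
  keep <- !is.na(per_of)
  pc <- patient_characteristics(patients[keep, , drop = FALSE], per_of[keep])
  md <- mission_distribution(included)
  thr <- threshold_proportions(included, threshold_min)
  scr <- scramble_rates(included)
  its_summary <- data.frame(
    quantity = c("beta0_min", "beta1_min_per_month", "beta2_min",
                 "beta3_min_per_month", "beta4_min", "p_beta2", "p_beta3",
                 "p_winter", "ma_theta", "sigma_min", "aicc", "r2",
                 "n_months"),
    value = c(model$beta0, model$beta1, model$beta2, model$beta3,
              model$beta4, model$p_beta2, model$p_beta3, model$p["winter"],
              model$ma_theta, model$sigma, model$aicc, model$r2, model$n),
    stringsAsFactors = FALSE)
  txt <- c(
    sprintf("Missions: %d records, %d included (%d excluded)",
            tally$total, tally$included, tally$total - tally$included),
    sprintf("ITS (%s errors): level change %.2f min (p = %.2f), slope change %.2f min/month (p = %.2f), winter effect %.2f min (p = %.3g)",
            model$error_label, model$beta2, model$p_beta2, model$beta3,
            model$p_beta3, model$beta4, model$p["winter"]),
    sprintf("Severe cases (NACA 4-7): %.1f%% pre vs %.1f%% post",
            100 * pc$severe_prop["pre"], 100 * pc$severe_prop["post"]),
    sprintf("Within %d min: %.1f%% pre vs %.1f%% post (all bases)",
            threshold_min, thr$pct_pre[thr$base_id == "all"],
            thr$pct_post[thr$base_id == "all"]),
    sprintf("Scrambles: %.1f%% pre vs %.1f%% post (all bases)",
            scr$pct_pre[scr$base_id == "all"],
            scr$pct_post[scr$base_id == "all"]))
  if (!is.null(areas$comparison))
    txt <- c(txt, apply(areas$comparison, 1, function(r)
      sprintf("Service area %s: %.0f -> %.0f km2 (%+.1f%%), median distance %+.1f km (HL %.1f [%.1f, %.1f], p = %.3g)",
              r[["base_id"]], as.numeric(r[["area_pre_km2"]]),
              as.numeric(r[["area_post_km2"]]),
              as.numeric(r[["area_change_pct"]]),
              as.numeric(r[["median_diff_km"]]),
              as.numeric(r[["hl_estimate_km"]]),
              as.numeric(r[["hl_ci_low"]]), as.numeric(r[["hl_ci_high"]]),
              as.numeric(r[["mw_p"]]))))
  structure(list(
    exclusions = as.data.frame(tally),
    patient_summary = pc$summary, icd10 = pc$icd10,
    mission_distribution = md$table,
    mission_distribution_p = md$p_value,
    threshold = thr, scrambles = scr,
    monthly = as.data.frame(monthly), its = its_summary,
    service_area = areas$comparison,
    summary_text = txt), class = "hems_report")
}

#' @export
print.hems_report <- function(x, ...) {
  cat("HEMS coordinator evaluation report\n")
  cat(paste0("  ", x$summary_text, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One CSV per table plus `summary.txt`. Output is deterministic: the same
#' inputs produce byte-identical files.
#'
#' @param report A `hems_report`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("exclusions", "patient_summary", "icd10",
              "mission_distribution", "threshold", "scrambles", "monthly",
              "its", "service_area")
  for (tb in tables)
    if (!is.null(report[[tb]]))
      utils::write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                       row.names = FALSE)
  writeLines(report$summary_text, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Run the full evaluation pipeline on synthetic data
#'
#' Generates a dataset from `config`, collapses multi-patient missions,
#' applies the inclusion filter, aggregates monthly means, flags the
#' intervention month and outlier months, selects and fits the segmented
#' ITS model, runs the service-area analysis and assembles the report.
#'
#' @param config A `sim_config`.
#' @param z_threshold Outlier-month threshold (SD units).
#' @param quantile Service-area distance-filter quantile.
#' @param threshold_min Response-time threshold (minutes).
#' @param candidates ITS error-model candidate set.
#' @return List with `sim`, `included`, `tally`, `monthly`, `model`,
#'   `areas`, `report`.
#' @export
run_pipeline <- function(config = default_config(),
                         z_threshold = 3, quantile = 0.95,
                         threshold_min = 45,
                         candidates = c("white", "ma1", "ar1", "sma12")) {
  sim <- generate_missions(config)
  missions <- collapse_multipatient(sim$missions, sim$patients)
  filt <- apply_inclusion_criteria(missions)
  n_months <- config$months_pre + config$months_post
  monthly <- aggregate_monthly(filt$included, config$study_start, n_months)
  tpi <- config$months_pre
  tpi_month <- month_seq(config$study_start, n_months)[tpi + 1L]
  monthly <- flag_excluded_months(monthly, tpi_month, z_threshold)
  model <- select_error_model(monthly, tpi, candidates)
  pat_inc <- sim$patients[sim$patients$mission_id %in%
                            filt$included$mission_id, , drop = FALSE]
  areas <- service_areas(filt$included, config$bases, quantile)
  report <- build_report(filt$included, pat_inc, filt$tally, monthly, model,
                         areas, threshold_min)
  list(sim = sim, included = filt$included, tally = filt$tally,
       monthly = monthly, model = model, areas = areas, report = report)
}
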