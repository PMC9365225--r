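#' Aggregate mission response times into a monthly series
#'
#' Builds one row per calendar month over the study window with the
#' arithmetic mean of that month's mission response times. Months with no
#' missions are present with a missing mean and are flagged. Month index
#' `t` is 0-based with `t = 0` at the first study month.
#'
#' @param missions Included mission table; response times are taken from a
#'   `response_min` column if present, otherwise computed with
#'   [response_time()].
#' @param study_start First study month `"YYYY-MM"`; default: month of the
#'   earliest mission.
#' @param n_months Number of months in the window; default: up to the month
#'   of the latest mission.
#' @return A `monthly_series` data frame with columns `month`, `t`,
#'   `n_missions`, `mean_response`, `included`, `exclusion_reason`.
#' @export
aggregate_monthly <- function(missions, study_start = NULL, n_months = NULL) {
  rt <- if ("response_min" %in% names(missions)) missions$response_min
        else as.numeric(response_time(missions))
  if (anyNA(rt))
    stop("all missions must have a valid response time; filter first",
         call. = FALSE)
  mlab <- format(missions$alarm_time, "%Y-%m")
  if (is.null(study_start)) study_start <- min(mlab)
  if (is.null(n_months))
    n_months <- month_index(max(mlab), study_start) + 1L
  months <- month_seq(study_start, n_months)
  n_m <- as.integer(table(factor(mlab, levels = months)))
  mean_r <- tapply(rt, factor(mlab, levels = months), mean)
  out <- data.frame(month = months, t = seq_len(n_months) - 1L,
                    n_missions = n_m,
                    mean_response = as.numeric(mean_r),
                    included = TRUE,
                    exclusion_reason = "none",
                    stringsAsFactors = FALSE)
  out$included[is.na(out$mean_response)] <- FALSE
  out$exclusion_reason[is.na(out$mean_response)] <- "no data"
  class(out) <- c("monthly_series", "data.frame")
  out
}

#' Flag the intervention month and outlier months
#'
#' The intervention month itself is excluded from the segmented fit (the
#' intervention took effect mid-month). In addition, any month whose mean is
#' more than `z_threshold` standard deviations from the mean of the other
#' non-intervention months (leave-one-out z-score) is flagged as an outlier.
#'
#' @param series A `monthly_series`.
#' @param tpi_month Calendar month `"YYYY-MM"` of the intervention.
#' @param z_threshold Outlier threshold in SD units (default 3).
#' @return The series with `included`/`exclusion_reason` updated.
#' @export
flag_excluded_months <- function(series, tpi_month, z_threshold = 3) {
  if (!tpi_month %in% series$month)
    stop("tpi_month is outside the study window", call. = FALSE)
  iv <- series$month == tpi_month
  series$included[iv] <- FALSE
  series$exclusion_reason[iv] <- "intervention month"
  cand <- which(!iv & !is.na(series$mean_response))
  x <- series$mean_response[cand]
  if (length(x) >= 3L) {
    for (j in seq_along(cand)) {
      rest <- x[-j]
      z <- (x[j] - mean(rest)) / stats::sd(rest)
      if (is.finite(z) && abs(z) > z_threshold) {
        series$included[cand[j]] <- FALSE
        series$exclusion_reason[cand[j]] <- "outlier"
      }
    }
  }
  series
}

#' Build the segmented-regression design matrix
#'
#' Columns are `intercept`, `t` (0-based month index), the post-intervention
#' step `u(t - tpi)` (1 for `t >= tpi`), the post-intervention ramp
#' `(t - tpi) * u(t - tpi)`, and the winter indicator (1 for October-March).
#' With the intervention month excluded from the data, the first included
#' post month carries step 1 and ramp 1.
#'
#' @param series A `monthly_series` (all rows; exclusion is handled by the
#'   fitting routine).
#' @param tpi 0-based month index of the intervention month.
#' @return Numeric matrix with one row per series row.
#' @export
build_design <- function(series, tpi) {
  if (tpi < min(series$t) || tpi > max(series$t))
    stop("tpi is outside the study window", call. = FALSE)
  t <- series$t
  step <- as.numeric(t >= tpi)
  ramp <- (t - tpi) * step
  winter <- as.numeric(is_winter(series$month))
  cbind(intercept = 1, t = t, step = step, ramp = ramp, winter = winter)
}

its_error_specs <- function() {
  list(white = list(n_arma = 0L, label = "white noise"),
       ma1   = list(n_arma = 1L, label = "MA(1)"),
       ar1   = list(n_arma = 1L, label = "AR(1)"),
       sma12 = list(n_arma = 1L, label = "seasonal MA, lag 12"))
}

# stationary error correlation matrix at calendar lags `dt` for a given
# structure; the scalar parameter lives in (-1, 1) for every structure
error_cor_matrix <- function(spec, par, dt) {
  switch(spec,
         white = diag(nrow(dt)),
         ma1 = {
           r <- par / (1 + par^2)
           ifelse(dt == 0, 1, ifelse(dt == 1, r, 0))
         },
         ar1 = par^dt,
         sma12 = {
           r <- par / (1 + par^2)
           ifelse(dt == 0, 1, ifelse(dt == 12, r, 0))
         },
         stop("unknown error structure", call. = FALSE))
}

# restricted (REML) profile log-likelihood of the correlation parameter,
# with beta and the error variance profiled out analytically
reml_profile <- function(par, spec, X, y, dt) {
  n <- length(y); p <- ncol(X)
  R <- error_cor_matrix(spec, par, dt)
  L <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  qrw <- qr(Xw)
  if (qrw$rank < p) return(-Inf)
  rss <- sum(qr.resid(qrw, yw)^2)
  s2 <- rss / (n - p)
  ldR <- 2 * sum(log(diag(L)))
  ldXX <- sum(log(abs(diag(qr.R(qrw)))^2))
  -0.5 * ((n - p) * log(2 * pi * s2) + ldR + ldXX + (n - p))
}

#' Fit the segmented interrupted-time-series model
#'
#' Fits the segmented regression
#' `f(t) = beta0 + beta1*t + beta2*u(t-tpi) + beta3*(t-tpi)*u(t-tpi) +
#' beta4*I_winter(t)` by restricted maximum likelihood (REML) under a
#' stationary error structure with closed-form correlation: white noise,
#' MA(1), AR(1) or seasonal MA at lag 12. The single correlation parameter
#' is profiled and maximised exactly in one dimension, and excluded months
#' keep their calendar spacing: correlations are evaluated at true month
#' lags across gaps. REML (rather than plain maximum likelihood) is used
#' because it removes the downward small-sample bias of the error-variance
#' estimate, which materially miscalibrates the `beta2`/`beta3` tests at a
#' few dozen months. Two-sided hypothesis tests on the level change `beta2`
#' and slope change `beta3` use a t reference distribution with `n - k`
#' degrees of freedom (`n` included months, `k = 5` mean parameters). AICc
#' is `AIC + 2k(k+1)/(n-k-1)` on the restricted likelihood with `k`
#' counting all estimated parameters including the error variance
#' (comparable across candidates because the mean structure is fixed); R2
#' is the ordinary coefficient of determination of the regression mean
#' against the observed monthly means, and is labelled as such.
#'
#' @param series A `monthly_series` (after [flag_excluded_months()]).
#' @param tpi 0-based index of the intervention month.
#' @param error_spec One of `"white"`, `"ma1"`, `"ar1"`, `"sma12"`.
#' @return An object of class `its_model`.
#' @export
fit_its <- function(series, tpi, error_spec = "ma1") {
  specs <- its_error_specs()
  if (!error_spec %in% names(specs))
    stop(sprintf("unknown error_spec '%s' (candidates: %s)", error_spec,
                 paste(names(specs), collapse = ", ")), call. = FALSE)
  sp <- specs[[error_spec]]
  X <- build_design(series, tpi)
  y <- series$mean_response
  y[!series$included] <- NA
  n <- sum(!is.na(y))
  if (n < 10L)
    stop("need at least 10 included months to fit", call. = FALSE)
  if (qr(X[!is.na(y), , drop = FALSE])$rank < ncol(X))
    stop("design matrix is rank deficient on the included months",
         call. = FALSE)
  # a series the design interpolates exactly has no error process to
  # estimate; return the exact least-squares solution directly
  obs <- !is.na(y)
  ols <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
  sst <- sum((y[obs] - mean(y[obs]))^2)
  if (sum(ols$residuals^2) <= 1e-12 * max(sst, 1)) {
    beta <- ols$coefficients
    yhat <- as.numeric(X %*% beta)
    zero <- stats::setNames(rep(0, 5),
                            c("intercept", "t", "step", "ramp", "winter"))
    return(structure(list(
      beta0 = unname(beta[1]), beta1 = unname(beta[2]),
      beta2 = unname(beta[3]), beta3 = unname(beta[4]),
      beta4 = unname(beta[5]),
      se_beta2 = 0, se_beta3 = 0, p_beta2 = NA_real_, p_beta3 = NA_real_,
      se = zero, p = zero + NA_real_,
      tpi = tpi, ma_theta = NA_real_, arma = numeric(0), sigma = 0,
      aicc = -Inf, aic = -Inf, r2 = 1, loglik = Inf,
      n = n, df = n - 5L, k = 6L, error_spec = error_spec,
      error_label = paste0(sp$label, " (exact fit)"),
      months = series$month, t = series$t, fitted_mean = yhat,
      observed = series$mean_response, included = series$included,
      vcov = NULL), class = "its_model"))
  }
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  to <- series$t[obs]
  dt <- abs(outer(to, to, "-"))
  if (sp$n_arma == 0L) {
    par_hat <- 0
  } else {
    opt <- stats::optimize(function(p) reml_profile(p, error_spec, Xo, yo,
                                                    dt),
                           interval = c(-0.999, 0.999), maximum = TRUE,
                           tol = 1e-8)
    par_hat <- opt$maximum
  }
  ll <- reml_profile(par_hat, error_spec, Xo, yo, dt)
  if (!is.finite(ll))
    stop(sprintf("ITS fit failed for error spec '%s': restricted likelihood is degenerate",
                 error_spec), call. = FALSE)
  R <- error_cor_matrix(error_spec, par_hat, dt)
  L <- chol(R)
  Xw <- backsolve(L, Xo, transpose = TRUE)
  yw <- backsolve(L, yo, transpose = TRUE)
  gfit <- stats::lm.fit(Xw, yw)
  beta <- gfit$coefficients
  p_n <- ncol(X)
  s2 <- sum(gfit$residuals^2) / (n - p_n)
  vc <- s2 * solve(crossprod(Xw))
  beta_se <- sqrt(diag(vc))
  k_all <- p_n + sp$n_arma + 1L       # mean + correlation + variance
  df <- n - p_n
  tstat <- beta / beta_se
  pval <- 2 * stats::pt(-abs(tstat), df = df)
  aic <- -2 * ll + 2 * k_all
  aicc <- if (n - k_all - 1 > 0) aic + 2 * k_all * (k_all + 1) /
    (n - k_all - 1) else NA_real_
  yhat <- as.numeric(X %*% beta)
  r2 <- 1 - sum((yo - yhat[obs])^2) / sum((yo - mean(yo))^2)
  beta_names <- c("intercept", "t", "step", "ramp", "winter")
  structure(list(
    beta0 = unname(beta[1]), beta1 = unname(beta[2]),
    beta2 = unname(beta[3]), beta3 = unname(beta[4]),
    beta4 = unname(beta[5]),
    se_beta2 = unname(beta_se[3]), se_beta3 = unname(beta_se[4]),
    p_beta2 = unname(pval[3]), p_beta3 = unname(pval[4]),
    se = stats::setNames(unname(beta_se), beta_names),
    p = stats::setNames(unname(pval), beta_names),
    tpi = tpi,
    ma_theta = if (error_spec == "ma1") par_hat else NA_real_,
    arma = if (sp$n_arma > 0L) stats::setNames(par_hat, error_spec)
           else numeric(0),
    sigma = sqrt(s2),
    aicc = aicc, aic = aic, r2 = r2, loglik = ll,
    n = n, df = df, k = k_all, error_spec = error_spec,
    error_label = sp$label,
    months = series$month, t = series$t, fitted_mean = yhat,
    observed = series$mean_response, included = series$included,
    vcov = vc), class = "its_model")
}

#' @export
print.its_model <- function(x, ...) {
  cat(sprintf("Segmented ITS model (%s errors), %d months, tpi = %d\n",
              x$error_label, x$n, x$tpi))
  cat(sprintf("  beta0 (level at t=0)     %8.3f min\n", x$beta0))
  cat(sprintf("  beta1 (pre slope)        %8.3f min/month\n", x$beta1))
  cat(sprintf("  beta2 (level change)     %8.3f min      p = %.3f\n",
              x$beta2, x$p_beta2))
  cat(sprintf("  beta3 (slope change)     %8.3f min/month p = %.3f\n",
              x$beta3, x$p_beta3))
  cat(sprintf("  beta4 (winter effect)    %8.3f min      p = %.3f\n",
              x$beta4, x$p["winter"]))
  if (!is.na(x$ma_theta))
    cat(sprintf("  MA(1) theta              %8.3f\n", x$ma_theta))
  cat(sprintf("  sigma %.3f  AICc %.2f  R2 %.3f\n", x$sigma, x$aicc, x$r2))
  invisible(x)
}

#' Select the error structure by AICc
#'
#' Fits every candidate error specification and returns the fit minimising
#' AICc. Ties (within `1e-8`) are broken by fewer estimated parameters, then
#' by candidate order. Candidates whose fit fails, does not converge, or
#' whose AICc is undefined (`n <= k + 1`) are rejected and reported in the
#' `diagnostics` attribute; if all candidates fail an error lists every
#' diagnostic.
#'
#' @inheritParams fit_its
#' @param candidates Character vector of error specs to compare.
#' @return The winning `its_model`, with attributes `candidates` (AICc
#'   table) and `diagnostics` (failure messages, if any).
#' @export
select_error_model <- function(series, tpi,
                               candidates = c("white", "ma1", "ar1",
                                              "sma12")) {
  if (length(candidates) == 0L)
    stop("candidate set must be non-empty", call. = FALSE)
  fits <- list(); diag <- character(0)
  for (cnd in candidates) {
    res <- tryCatch(fit_its(series, tpi, cnd), error = function(e)
      conditionMessage(e))
    if (inherits(res, "its_model")) {
      if (is.na(res$aicc))
        diag[cnd] <- sprintf("'%s': AICc undefined (n = %d <= k + 1 = %d)",
                             cnd, res$n, res$k + 1L)
      else fits[[cnd]] <- res
    } else diag[cnd] <- res
  }
  if (length(fits) == 0L)
    stop(paste(c("all candidate error models failed:", diag),
               collapse = "\n  "), call. = FALSE)
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  ks <- vapply(fits, `[[`, numeric(1), "k")
  best <- aiccs <= min(aiccs) + 1e-8
  pick <- names(fits)[best][order(ks[best],
                                  match(names(fits)[best], candidates))][1]
  out <- fits[[pick]]
  attr(out, "candidates") <- data.frame(
    error_spec = names(fits), aicc = unname(aiccs), k = unname(ks),
    r2 = vapply(fits, `[[`, numeric(1), "r2"), stringsAsFactors = FALSE)
  attr(out, "diagnostics") <- diag
  out
}

#' Fitted deterministic mean and counterfactual trend
#'
#' `predict_mean()` evaluates the full fitted mean (with step and ramp);
#' `counterfactual()` evaluates `beta0 + beta1*t + beta4*I_winter(t)` — the
#' expected trajectory had the intervention not occurred, i.e. the pre
#' trend extrapolated with seasonality. For pre months the two coincide;
#' after the intervention their difference is `beta2 + beta3*(t - tpi)`.
#'
#' @param model An `its_model`.
#' @param t 0-based month indices (default: the fitted window).
#' @return Numeric vector of minutes.
#' @export
counterfactual <- function(model, t = model$t) {
  months <- int_to_month(month_to_int(model$months[1]) - model$t[1] + t)
  model$beta0 + model$beta1 * t + model$beta4 * as.numeric(is_winter(months))
}

#' @rdname counterfactual
#' @export
predict_mean <- function(model, t = model$t) {
  months <- int_to_month(month_to_int(model$months[1]) - model$t[1] + t)
  step <- as.numeric(t >= model$tpi)
  model$beta0 + model$beta1 * t + model$beta2 * step +
    model$beta3 * (t - model$tpi) * step +
    model$beta4 * as.numeric(is_winter(months))
}

#' Plot an ITS fit
#'
#' Observed monthly means (excluded months hollow), the fitted segmented
#' mean and the counterfactual trend over the post period.
#'
#' @param model An `its_model`.
#' @param file Optional output path (PNG/PDF inferred from extension).
#' @return The ggplot object, invisibly (requires ggplot2).
#' @export
plot_its <- function(model, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- data.frame(t = model$t, observed = model$observed,
                  included = model$included,
                  fitted = predict_mean(model),
                  counterfactual = counterfactual(model))
  d$segment <- ifelse(d$t < model$tpi, "pre", "post")
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     shape = .data$included)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted,
                                    group = .data$segment), colour = "red") +
    ggplot2::geom_line(data = d[d$t >= model$tpi, ],
                       ggplot2::aes(y = .data$counterfactual),
                       colour = "blue", linetype = 2) +
    ggplot2::geom_vline(xintercept = model$tpi - 0.5, linetype = 3) +
    ggplot2::labs(x = "month index", y = "mean response time (min)")
  if (!is.null(file)) ggplot2::ggsave(file, g, width = 8, height = 4.5)
  invisible(g)
}
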