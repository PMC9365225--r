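test_that("monthly aggregation takes arithmetic means per calendar month", {
  m <- mk_missions(3, response_min = c(30, 31, 32))
  s <- aggregate_monthly(m)
  expect_equal(nrow(s), 1L)
  expect_equal(s$mean_response, 31)
  expect_equal(s$n_missions, 3L)
  # single-mission month
  s1 <- aggregate_monthly(mk_missions(1, response_min = 27.5))
  expect_equal(s1$mean_response, 27.5)
})

test_that("mission-weighted mean of monthly means equals the grand mean", {
  sim <- generate_missions(tiny_config(seed = 2L))
  s <- aggregate_monthly(sim$missions)
  weighted <- sum(s$mean_response * s$n_missions) / sum(s$n_missions)
  expect_equal(weighted, mean(sim$missions$response_min), tolerance = 1e-12)
})

test_that("months with no missions appear with a missing, flagged mean", {
  m <- mk_missions(2)
  s <- aggregate_monthly(m, study_start = "2018-04", n_months = 3)
  expect_equal(s$month, c("2018-04", "2018-05", "2018-06"))
  expect_true(is.na(s$mean_response[1]))
  expect_false(s$included[1])
  expect_equal(s$exclusion_reason[1], "no data")
})

test_that("intervention month and planted 3.4-SD outlier are flagged", {
  set.seed(10)
  s <- make_series(beta = c(31, 0.05, 0, 0, 1.1), theta = 0.3, sd = 1)
  base <- s$mean_response[-25]
  s$mean_response[36] <- mean(base) + 3.4 * sd(base)   # December 2019
  flagged <- flag_excluded_months(s, "2019-01", 3)
  expect_equal(flagged$exclusion_reason[25], "intervention month")
  expect_equal(flagged$exclusion_reason[36], "outlier")
  # 24 included pre months, 10 included post months
  expect_equal(sum(flagged$included & flagged$t < 24), 24L)
  expect_equal(sum(flagged$included & flagged$t > 24), 10L)
})

test_that("a flat series flags only the intervention month", {
  s <- make_series(beta = c(31, 0, 0, 0, 0), theta = 0, sd = 0)
  flagged <- flag_excluded_months(s, "2019-01", 3)
  expect_equal(sum(!flagged$included), 1L)
  expect_equal(flagged$exclusion_reason[25], "intervention month")
  expect_error(flag_excluded_months(s, "2030-01"), "window")
})

test_that("design matrix encodes step, ramp and winter as specified", {
  s <- make_series()
  X <- build_design(s, 24)
  expect_equal(unname(X[1, ]), c(1, 0, 0, 0, 1))      # Jan 2017, winter
  expect_equal(unname(X[25, c("step", "ramp")]), c(1, 0))  # intervention month
  expect_equal(unname(X[26, c("step", "ramp")]), c(1, 1))  # first post month
  expect_true(all(X[1:24, "step"] == 0) && all(X[1:24, "ramp"] == 0))
  expect_equal(unname(X[, "winter"]),
               as.numeric(is_winter(s$month)))
  expect_error(build_design(s, 99), "window")
})

test_that("noiseless series recovers the generating coefficients exactly", {
  s <- make_series(beta = c(31, 0.1, -2, -0.3, 1.1), theta = 0, sd = 0)
  s <- flag_excluded_months(s, "2019-01", 3)
  fit <- fit_its(s, 24, "white")
  expect_equal(c(fit$beta0, fit$beta1, fit$beta2, fit$beta3, fit$beta4),
               c(31, 0.1, -2, -0.3, 1.1), tolerance = 1e-6)
  expect_gt(fit$r2, 1 - 1e-9)
})

test_that("white-noise fit equals ordinary least squares", {
  set.seed(5)
  s <- make_series(beta = c(31, 0.05, -1, -0.2, 1.1), theta = 0, sd = 1.5)
  s <- flag_excluded_months(s, "2019-01", 3)
  fit <- fit_its(s, 24, "white")
  X <- build_design(s, 24)
  keep <- s$included
  ols <- lm.fit(X[keep, ], s$mean_response[keep])
  expect_equal(unname(c(fit$beta0, fit$beta1, fit$beta2, fit$beta3,
                        fit$beta4)),
               unname(ols$coefficients), tolerance = 1e-8)
})

test_that("MA(1) REML fit agrees with an independent gls implementation", {
  set.seed(21)
  s <- make_series(beta = c(31, 0.05, -2, -0.2, 1.1), theta = 0.4, sd = 1.5)
  s <- flag_excluded_months(s, "2019-01", 3)
  fit <- fit_its(s, 24, "ma1")
  d <- data.frame(y = s$mean_response, t = s$t,
                  step = as.numeric(s$t >= 24),
                  ramp = (s$t - 24) * (s$t >= 24),
                  w = as.numeric(is_winter(s$month)))[s$included, ]
  ref <- nlme::gls(y ~ t + step + ramp + w, data = d,
                   correlation = nlme::corARMA(q = 1, form = ~ t),
                   method = "REML")
  expect_equal(unname(coef(ref)),
               c(fit$beta0, fit$beta1, fit$beta2, fit$beta3, fit$beta4),
               tolerance = 1e-4)
  tt <- summary(ref)$tTable
  expect_equal(unname(tt["step", "Std.Error"]), fit$se_beta2,
               tolerance = 1e-3)
  expect_equal(unname(tt["step", "p-value"]), fit$p_beta2, tolerance = 1e-3)
  expect_equal(unname(tt["ramp", "p-value"]), fit$p_beta3, tolerance = 1e-3)
})

test_that("MA(1) fit recovers a strong level change on one realisation", {
  set.seed(77)
  s <- make_series(beta = c(31, 0.05, -6, -0.2, 1.1), theta = 0.3, sd = 1.2)
  s <- flag_excluded_months(s, "2019-01", 3)
  fit <- fit_its(s, 24, "ma1")
  expect_lt(abs(fit$beta2 - (-6)), 4 * fit$se_beta2)
  expect_lt(fit$p_beta2, 0.05)
  expect_true(is.finite(fit$aicc) && fit$p_beta2 >= 0 && fit$p_beta2 <= 1)
})

test_that("error-model selection minimises AICc and reports diagnostics", {
  set.seed(6)
  s <- make_series(theta = 0, sd = 1)
  s <- flag_excluded_months(s, "2019-01", 3)
  best <- select_error_model(s, 24)
  cand <- attr(best, "candidates")
  expect_true(best$error_spec %in% cand$error_spec)
  expect_equal(best$aicc, min(cand$aicc))
  # a parsimony-favouring tie cannot prefer the larger model
  tied <- cand[abs(cand$aicc - min(cand$aicc)) <= 1e-8, ]
  expect_equal(best$k, min(tied$k))
  expect_error(select_error_model(s, 24, character(0)), "non-empty")
})

test_that("selection fails loudly when every candidate fails", {
  s <- make_series(months_pre = 6L, months_post = 3L)   # < 10 months
  expect_error(select_error_model(s, 6), "all candidate error models failed")
})

test_that("counterfactual is the pre trend extrapolated with seasonality", {
  set.seed(8)
  s <- make_series(beta = c(31, 0.05, -2, -0.3, 1.1), theta = 0, sd = 1)
  s <- flag_excluded_months(s, "2019-01", 3)
  fit <- fit_its(s, 24, "white")
  pre_t <- 0:23
  expect_equal(counterfactual(fit, pre_t), predict_mean(fit, pre_t))
  post_t <- 25:35
  expect_equal(predict_mean(fit, post_t) - counterfactual(fit, post_t),
               fit$beta2 + fit$beta3 * (post_t - 24), tolerance = 1e-10)
  # with no intervention terms the two trajectories coincide everywhere
  s0 <- make_series(beta = c(31, 0.05, 0, 0, 1.1), theta = 0, sd = 0)
  s0 <- flag_excluded_months(s0, "2019-01", 3)
  f0 <- fit_its(s0, 24, "white")
  expect_equal(counterfactual(f0, post_t), predict_mean(f0, post_t),
               tolerance = 1e-6)
})

test_that("adding a constant shifts only the intercept", {
  set.seed(9)
  s <- make_series(theta = 0.3, sd = 1)
  s <- flag_excluded_months(s, "2019-01", 3)
  s2 <- s; s2$mean_response <- s2$mean_response + 10
  f1 <- fit_its(s, 24, "ma1")
  f2 <- fit_its(s2, 24, "ma1")
  expect_equal(f2$beta0, f1$beta0 + 10, tolerance = 1e-4)
  expect_equal(c(f2$beta1, f2$beta2, f2$beta3, f2$beta4),
               c(f1$beta1, f1$beta2, f1$beta3, f1$beta4), tolerance = 1e-4)
})

test_that("shifting the time origin leaves effects and p-values unchanged", {
  set.seed(12)
  s <- make_series(theta = 0.3, sd = 1)
  s <- flag_excluded_months(s, "2019-01", 3)
  s2 <- s; s2$t <- s2$t + 12
  f1 <- fit_its(s, 24, "ma1")
  f2 <- fit_its(s2, 24 + 12, "ma1")
  expect_equal(f2$beta2, f1$beta2, tolerance = 1e-4)
  expect_equal(f2$beta3, f1$beta3, tolerance = 1e-4)
  expect_equal(f2$p_beta2, f1$p_beta2, tolerance = 1e-3)
  expect_equal(f2$p_beta3, f1$p_beta3, tolerance = 1e-3)
  expect_equal(predict_mean(f2, s2$t), predict_mean(f1, s$t),
               tolerance = 1e-3)
})

test_that("R2 does not decrease when step and ramp join the pre-trend model", {
  set.seed(14)
  for (i in 1:5) {
    s <- make_series(beta = c(31, 0.05, runif(1, -3, 0), runif(1, -0.3, 0),
                              1.1), theta = 0, sd = 1)
    s <- flag_excluded_months(s, "2019-01", 3)
    fit <- fit_its(s, 24, "white")
    keep <- s$included
    reduced <- lm(s$mean_response[keep] ~ s$t[keep] +
                    as.numeric(is_winter(s$month[keep])))
    expect_gte(fit$r2 + 1e-10, summary(reduced)$r.squared)
  }
})
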