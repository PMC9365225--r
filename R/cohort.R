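#' Pearson chi-square test on a 2xk (or rxk) count table
#'
#' Pearson's chi-square statistic without continuity correction, with a
#' two-sided p-value from the chi-square distribution. For a 2x2 table the
#' statistic equals the squared two-proportion z-statistic.
#'
#' @param tab Matrix of non-negative integer counts, at least 2x2.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_2xk <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table must be at least 2x2", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in count table", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test: exact enumeration for small untied samples,
#' otherwise the normal approximation with tie correction (the standard
#' behaviour of [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples (non-empty).
#' @return List with `U` (statistic for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("samples must be non-empty", call. = FALSE)
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                             correct = TRUE))
  list(U = unname(res$statistic), p_value = res$p.value,
       method = res$method)
}

#' Hodges-Lehmann shift estimate with confidence interval
#'
#' The point estimate is the median of all `n*m` pairwise differences
#' `x_i - y_j`. The confidence interval inverts the Mann-Whitney test: with
#' `k` the lower `alpha/2` critical value of the U distribution (exact via
#' [stats::qwilcox()] when `n*m <= 10000`, else the normal approximation),
#' the interval runs from the `(k+1)`-th to the `(n*m-k)`-th ordered
#' pairwise difference.
#'
#' @param x,y Numeric samples (non-empty); the estimate is the shift of `x`
#'   relative to `y`.
#' @param level Confidence level (default 0.95).
#' @return List with `estimate`, `ci` (length-2 vector), `level`.
#' @export
hodges_lehmann_ci <- function(x, y, level = 0.95) {
  if (length(x) == 0L || length(y) == 0L)
    stop("samples must be non-empty", call. = FALSE)
  n <- length(x); m <- length(y)
  d <- sort(as.vector(outer(x, y, "-")))
  nm <- n * m
  est <- stats::median(d)
  alpha <- 1 - level
  if (nm <= 10000) {
    k <- stats::qwilcox(alpha / 2, n, m)
    # qwilcox returns smallest u with P(U <= u) >= alpha/2; step back so the
    # tail stays below alpha/2
    if (k > 0 && stats::pwilcox(k, n, m) > alpha / 2) k <- k - 1L
  } else {
    mu <- nm / 2
    sdv <- sqrt(nm * (n + m + 1) / 12)
    k <- floor(mu + stats::qnorm(alpha / 2) * sdv)
  }
  k <- max(0, min(k, floor((nm - 1) / 2)))
  list(estimate = est, ci = c(d[k + 1], d[nm - k]), level = level)
}

#' Welch / Student two-sample t test
#'
#' Thin wrapper over [stats::t.test()]; Welch's unequal-variance form by
#' default, pooled-variance Student form on request.
#'
#' @param x,y Numeric samples.
#' @param pooled Use the pooled-variance (classical Student) form.
#' @return List with `estimate` (mean difference `x - y`), `p_value`, `ci`.
#' @export
t_test_means <- function(x, y, pooled = FALSE) {
  res <- stats::t.test(x, y, var.equal = pooled)
  list(estimate = unname(diff(rev(res$estimate))), p_value = res$p.value,
       ci = unname(res$conf.int))
}

#' Proportion of missions within a response-time threshold
#'
#' For each base and for the region, the fraction of missions whose response
#' time is less than or equal to `threshold_min` ("within" read as
#' inclusive), split by period, with counts, the post-minus-pre percentage
#' difference and a chi-square p-value per row.
#'
#' @param missions Included mission table with `base_id`, `period` and
#'   response times (`response_min` column or derivable timestamps).
#' @param threshold_min Threshold in minutes (default 45, the national
#'   90%-coverage goal).
#' @return `data.frame` with one row per base plus `"all"`.
#' @export
threshold_proportions <- function(missions, threshold_min = 45) {
  rt <- if ("response_min" %in% names(missions)) missions$response_min
        else as.numeric(response_time(missions))
  ok <- rt <= threshold_min
  groups <- c("all", sort(unique(missions$base_id)))
  rows <- lapply(groups, function(g) {
    sel <- if (g == "all") rep(TRUE, nrow(missions))
           else missions$base_id == g
    pre <- sel & missions$period == "pre"
    post <- sel & missions$period == "post"
    n_pre <- sum(pre); n_post <- sum(post)
    if (n_pre == 0L || n_post == 0L) return(NULL)
    w_pre <- sum(ok & pre); w_post <- sum(ok & post)
    p <- tryCatch(chi_square_2xk(rbind(c(w_pre, n_pre - w_pre),
                                       c(w_post, n_post - w_post)))$p_value,
                  error = function(e) NA_real_)
    data.frame(base_id = g,
               n_pre = n_pre, within_pre = w_pre,
               pct_pre = 100 * w_pre / n_pre,
               n_post = n_post, within_post = w_post,
               pct_post = 100 * w_post / n_post,
               diff_pct = 100 * (w_post / n_post - w_pre / n_pre),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
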