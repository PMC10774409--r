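# Effect-size machinery: Cohen's d of warming (warmed vs ambient) per year,
# OLS and standardized-major-axis trends of the d trajectory, ln response
# ratios, and the early/late stage contrast.

#' Cohen's d (pooled-SD form)
#'
#' d = (mean_t - mean_c) / s_pooled with
#' s_pooled^2 = ((n_t-1)s_t^2 + (n_c-1)s_c^2) / (n_t + n_c - 2).
#' Positive d means the treated (warmed) group exceeds the control.
#'
#' @param treated,control numeric vectors, each of length >= 2.
#' @param hedges apply the small-sample (Hedges' g) correction
#'   `1 - 3/(4(n_t+n_c)-9)`; default off.
#' @return dimensionless effect size.
#' @export
cohens_d <- function(treated, control, hedges = FALSE) {
  treated <- treated[!is.na(treated)]
  control <- control[!is.na(control)]
  nt <- length(treated); nc <- length(control)
  if (nt < 2 || nc < 2)
    ws_stop("cohens_d needs >= 2 observations per group")
  sp2 <- ((nt - 1) * stats::var(treated) + (nc - 1) * stats::var(control)) /
    (nt + nc - 2)
  if (sp2 <= 0) ws_stop("cohens_d undefined: pooled variance is zero")
  d <- (mean(treated) - mean(control)) / sqrt(sp2)
  if (hedges) d <- d * (1 - 3 / (4 * (nt + nc) - 9))
  d
}

#' Ordinary least squares trend
#'
#' Slope, intercept, adjusted R-squared and the two-sided p-value of the
#' slope t-test for a simple linear regression of `y` on `x`.
#'
#' @param x,y numeric vectors (NA pairs dropped with a message).
#' @return list with `slope`, `intercept`, `r2_adjusted`, `p`, `slope_se`,
#'   `n`.
#' @export
trend_ols <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  if (sum(!keep) > 0)
    message(sprintf("trend_ols: dropped %d incomplete point(s)", sum(!keep)))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) ws_stop("trend_ols needs >= 3 complete points")
  if (stats::var(x) == 0) ws_stop("trend_ols: x is constant")
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (se == 0) {
    if (slope == 0) 1 else 0
  } else {
    2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  }
  list(slope = slope, intercept = intercept, r2_adjusted = r2_adj, p = p,
       slope_se = se, n = n)
}

#' Standardized major axis slope
#'
#' slope_SMA = sign(corr(x, y)) x sd(y)/sd(x); symmetric in the sense that
#' swapping x and y yields the reciprocal slope.
#'
#' @param x,y numeric vectors with positive variance.
#' @return the SMA slope.
#' @export
trend_sma <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) ws_stop("trend_sma needs >= 3 complete points")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    ws_stop("trend_sma: zero variance in x or y")
  r <- stats::cor(x, y)
  s <- if (r < 0) -1 else 1
  s * stats::sd(y) / stats::sd(x)
}

#' ln response ratio
#'
#' RR = ln(mean_treated / mean_control). Both means must be strictly
#' positive for the log-normal approximation to hold.
#'
#' @param mean_treated,mean_control positive numbers.
#' @return dimensionless log ratio.
#' @export
response_ratio <- function(mean_treated, mean_control) {
  if (any(mean_treated <= 0) || any(mean_control <= 0))
    ws_stop("response_ratio requires strictly positive means")
  log(mean_treated) - log(mean_control)
}

#' Warming effect-size trajectory for one variable
#'
#' For each sampling year, Cohen's d of warmed vs ambient across blocks
#' within the given management; then OLS and SMA trends of d against
#' calendar year.
#'
#' @param measurements a [measurement_table()].
#' @param design a [study_design()].
#' @param variable measurement column name.
#' @param management `"conservation"` or `"conventional"`.
#' @param hedges passed to [cohens_d()].
#' @return object of class `effect_size_series`: list with `variable`,
#'   `management`, `per_year` (data.frame year/d/n_warmed/n_ambient),
#'   `trend_slope`, `trend_slope_sma`, `trend_r2_adjusted`, `trend_p`,
#'   `trend_slope_se`.
#' @export
effect_size_series <- function(measurements, design, variable, management,
                               hedges = FALSE) {
  if (!variable %in% names(measurements$data))
    ws_stop(sprintf("variable '%s' not in measurement table", variable))
  s <- design$samples
  m <- merge(measurements$data[c("sample_id", variable)], s, by = "sample_id")
  m <- m[m$management == management, ]
  drop_na <- sum(is.na(m[[variable]]))
  if (drop_na > 0)
    message(sprintf("effect_size_series: dropped %d NA measurement(s)", drop_na))
  m <- m[!is.na(m[[variable]]), ]
  years <- sort(unique(m$year))
  rows <- lapply(years, function(yr) {
    w <- m[[variable]][m$year == yr & m$warming == "warmed"]
    a <- m[[variable]][m$year == yr & m$warming == "ambient"]
    d <- if (length(w) >= 2 && length(a) >= 2)
      tryCatch(cohens_d(w, a, hedges = hedges), error = function(e) NA_real_)
    else NA_real_
    data.frame(year = yr, d = d, n_warmed = length(w), n_ambient = length(a))
  })
  per_year <- do.call(rbind, rows)
  usable <- per_year[!is.na(per_year$d), ]
  trend <- list(slope = NA_real_, r2_adjusted = NA_real_, p = NA_real_,
                slope_se = NA_real_)
  sma <- NA_real_
  if (nrow(usable) >= 3) {
    trend <- trend_ols(usable$year, usable$d)
    sma <- tryCatch(trend_sma(usable$year, usable$d),
                    error = function(e) NA_real_)
  } else {
    message(sprintf(
      "effect_size_series: only %d usable year(s); trend not fit",
      nrow(usable)))
  }
  structure(
    list(variable = variable, management = management, per_year = per_year,
         trend_slope = trend$slope, trend_slope_sma = sma,
         trend_r2_adjusted = trend$r2_adjusted, trend_p = trend$p,
         trend_slope_se = trend$slope_se),
    class = "effect_size_series")
}

#' @export
print.effect_size_series <- function(x, ...) {
  cat(sprintf(
    "effect_size_series: %s (%s)\n  trend slope %.4g (SMA %.4g), adj R2 %.3f, p %.3g\n",
    x$variable, x$management, x$trend_slope, x$trend_slope_sma,
    x$trend_r2_adjusted, x$trend_p))
  print(x$per_year, row.names = FALSE)
  invisible(x)
}

#' Early vs late stage contrast of an effect-size trajectory
#'
#' Splits the study years at `split_year` (years <= split_year are "early")
#' and contrasts the mean Cohen's d between stages.
#'
#' @param series an [effect_size_series()].
#' @param split_year last calendar year of the early stage (default 2015,
#'   i.e. early 2010-2015 vs late 2016-2020).
#' @return list of class `stage_contrast` with `early_years`, `late_years`,
#'   `early_mean_d`, `late_mean_d`, `difference`.
#' @export
stage_contrast <- function(series, split_year = 2015) {
  py <- series$per_year
  py <- py[!is.na(py$d), ]
  early <- py[py$year <= split_year, ]
  late <- py[py$year > split_year, ]
  if (nrow(early) == 0 || nrow(late) == 0)
    ws_stop("stage_contrast: each stage needs >= 1 year with a defined d")
  structure(
    list(variable = series$variable,
         early_years = early$year, late_years = late$year,
         early_mean_d = mean(early$d), late_mean_d = mean(late$d),
         difference = mean(late$d) - mean(early$d)),
    class = "stage_contrast")
}
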