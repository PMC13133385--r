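# Comparison statistics: Deming errors-in-variables regression, deviation
# degree (Cohen's-d style), 100-m depth binning, year-difference
# correlation, Monte Carlo propagation of per-sample uncertainty, and the
# linear flux-scaling argument.

#' Deming regression
#'
#' Closed-form errors-in-variables straight-line fit for data with
#' measurement error in both axes, governed by `delta`, the ratio of the
#' y- to the x-error variance. delta -> Inf recovers OLS of y on x;
#' delta -> 0 recovers the inverse of the OLS of x on y. The slope
#' standard error is estimated by leave-one-out jackknife; `s_est` is the
#' RMS residual in y-units (vertical residuals weighted for the orthogonal
#' direction), the average distance between the observations and the line.
#'
#' @param x,y numeric vectors, n >= 3
#' @param delta error-variance ratio var(err_y)/var(err_x), > 0 (default 1)
#' @return list with slope, slope_se, intercept, s_est, n, delta
#' @export
deming_fit <- function(x, y, delta = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("deming_fit: need at least 3 finite pairs")
  if (delta <= 0) stop("deming_fit: delta must be > 0")
  est <- function(x, y) {
    sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
    if (sxx == 0 && syy == 0) stop("deming_fit: zero variance in both axes")
    if (sxy == 0) stop("deming_fit: zero covariance, slope undefined")
    D <- syy - delta * sxx
    R <- sqrt(D^2 + 4 * delta * sxy^2)
    # the two forms are algebraically identical; the second avoids
    # catastrophic cancellation when delta*sxx dominates syy
    b <- if (D >= 0) (D + R) / (2 * sxy) else 2 * delta * sxy / (R - D)
    c(slope = b, intercept = mean(y) - b * mean(x))
  }
  co <- est(x, y)
  resid <- (y - co["intercept"] - co["slope"] * x) /
    sqrt(1 + co["slope"]^2 / delta)
  s_est <- sqrt(sum(resid^2) / (n - 2))
  jack <- vapply(seq_len(n), function(i) est(x[-i], y[-i])["slope"],
                 numeric(1))
  slope_se <- sqrt((n - 1) / n * sum((jack - mean(jack))^2))
  list(slope = unname(co["slope"]), slope_se = slope_se,
       intercept = unname(co["intercept"]), s_est = unname(s_est),
       n = n, delta = delta)
}

#' Deviation degree (standardized mean difference)
#'
#' DD = (M_F - M_S) / sqrt(SD_F^2 + SD_S^2): the float-minus-ship mean
#' difference scaled by the combined (root-sum-square, not pooled) spread.
#' Negative DD means the float mean is below the ship mean. The standard
#' error uses the large-sample Cohen's-d approximation
#' sqrt((nF + nS)/(nF nS) + DD^2 / (2 (nF + nS))).
#'
#' @param float_values,ship_values numeric vectors
#' @return list with dd, se, m_f, m_s, sd_f, sd_s, n_f, n_s
#' @export
deviation_degree <- function(float_values, ship_values) {
  f <- float_values[is.finite(float_values)]
  s <- ship_values[is.finite(ship_values)]
  if (!length(f) || !length(s)) stop("deviation_degree: empty group")
  sdf <- stats::sd(f); sds <- stats::sd(s)
  if (isTRUE(all.equal(sdf + sds, 0))) {
    stop("deviation_degree: both standard deviations are zero")
  }
  dd <- (mean(f) - mean(s)) / sqrt(sdf^2 + sds^2)
  nf <- length(f); ns <- length(s)
  se <- sqrt((nf + ns) / (nf * ns) + dd^2 / (2 * (nf + ns)))
  list(dd = dd, se = se, m_f = mean(f), m_s = mean(s),
       sd_f = sdf, sd_s = sds, n_f = nf, n_s = ns)
}

#' Depth-binned float-ship comparison
#'
#' Bins matched level pairs into half-open depth intervals
#' [k w, (k+1) w) on the float depth (default w = 100 m) and reports, per
#' bin and variable, the float and ship means and SDs, the mean and SD of
#' the float-minus-ship difference, the deviation degree with its standard
#' error, and counts. Empty bins are omitted.
#'
#' @param pairs matched pair table with `<var>_f`, `<var>_s`, `d_<var>`
#' @param variable variable name, e.g. "ph_insitu"
#' @param width bin width, m
#' @return data.frame, one row per occupied bin
#' @export
depth_binned_profiles <- function(pairs, variable, width = 100) {
  fv <- pairs[[paste0(variable, "_f")]]
  sv <- pairs[[paste0(variable, "_s")]]
  dv <- pairs[[paste0("d_", variable)]]
  bin <- floor(pairs$float_depth / width)
  rows <- lapply(sort(unique(bin)), function(b) {
    i <- which(bin == b & is.finite(dv))
    if (!length(i)) return(NULL)
    dd <- if (length(i) >= 2 && (stats::sd(fv[i]) + stats::sd(sv[i])) > 0) {
      deviation_degree(fv[i], sv[i])
    } else list(dd = NA_real_, se = NA_real_)
    data.frame(depth_min = b * width, depth_max = (b + 1) * width,
               n = length(i),
               mean_f = mean(fv[i]), mean_s = mean(sv[i]),
               sd_f = stats::sd(fv[i]), sd_s = stats::sd(sv[i]),
               mean_diff = mean(dv[i]), sd_diff = stats::sd(dv[i]),
               dd = dd$dd, dd_se = dd$se)
  })
  do.call(rbind, rows)
}

#' Correlation of float-ship differences with sampling-year difference
#'
#' OLS of the matched difference on the float-minus-ship year difference,
#' with Pearson r and its two-sided p-value; a flat relationship indicates
#' the diagnosed bias is not an artefact of the float data being more
#' recent.
#'
#' @param pairs matched pair table with `year_diff`
#' @param variable variable name (uses column `d_<variable>`)
#' @return list with slope, intercept, r, p, n
#' @export
year_difference_correlation <- function(pairs, variable) {
  d <- pairs[[paste0("d_", variable)]]
  ok <- is.finite(d) & is.finite(pairs$year_diff)
  x <- pairs$year_diff[ok]; d <- d[ok]
  if (stats::var(x) == 0) {
    stop("year_difference_correlation: constant year difference")
  }
  m <- stats::lm(d ~ x)
  ct <- stats::cor.test(x, d)
  list(slope = unname(stats::coef(m)[2]),
       intercept = unname(stats::coef(m)[1]),
       r = unname(ct$estimate), p = ct$p.value, n = length(d))
}

#' Monte Carlo propagation of per-sample pCO2 uncertainty
#'
#' Repeats the following `reps` times: draw `n` float values mu_f + G(0,
#' sd_f) and `n` ship values mu_s + G(0, sd_s), form the n pairwise
#' differences and average them. Reports the distribution of the rep
#' means, its 2.5/97.5 percentiles, and the 95% half-width (half the
#' central-interval width), quantifying how much random per-sample error
#' can move the mean difference.
#'
#' @param n pairs per repetition (default 724, the matched profile count)
#' @param mu_f,sd_f float mean and per-sample SD, uatm (defaults 400, 11)
#' @param mu_s,sd_s ship mean and per-sample SD, uatm (defaults 383, 12)
#' @param reps repetitions (default 1000)
#' @param seed RNG seed
#' @return list with mean_diffs (length `reps`), mean, ci (2.5/97.5
#'   percentiles), half_width, and the configuration
#' @export
monte_carlo_delta <- function(n = 724, mu_f = 400, sd_f = 11,
                              mu_s = 383, sd_s = 12, reps = 1000,
                              seed = 1) {
  stopifnot(n >= 1, reps >= 1, sd_f >= 0, sd_s >= 0)
  set.seed(seed)
  md <- vapply(seq_len(reps), function(r) {
    mean((mu_f + stats::rnorm(n, 0, sd_f)) - (mu_s + stats::rnorm(n, 0, sd_s)))
  }, numeric(1))
  ci <- unname(stats::quantile(md, c(0.025, 0.975)))
  list(mean_diffs = md, mean = mean(md), ci = ci,
       half_width = diff(ci) / 2,
       config = list(n = n, mu_f = mu_f, sd_f = sd_f, mu_s = mu_s,
                     sd_s = sd_s, reps = reps, seed = seed))
}

#' Scale a surface pCO2 bias to an air-sea flux estimate
#'
#' Linear scaling of the Southern Ocean float-based annual flux with the
#' surface pCO2 bias: flux = base_flux - sensitivity x bias, with the
#' published sensitivity of 0.21 Pg C yr-1 per 4 uatm. Negative fluxes are
#' ocean uptake (ingassing).
#'
#' @param bias_uatm surface pCO2 bias, uatm
#' @param base_flux unadjusted float-based flux, Pg C yr-1 (default +0.35)
#' @param sensitivity Pg C yr-1 per uatm (default 0.21/4)
#' @return implied flux, Pg C yr-1
#' @export
flux_scaling <- function(bias_uatm, base_flux = 0.35, sensitivity = 0.21 / 4) {
  base_flux - sensitivity * bias_uatm
}

#' Deming comparison table across variables
#'
#' Per-variable summary of matched (screened) float-ship pairs: Deming
#' slope with jackknife SE, regression standard error, mean difference
#' (float minus ship) and mean relative difference (F - S)/S x 100%.
#' Variables with fewer than 3 finite pairs are omitted with a warning.
#'
#' @param pairs matched pair table
#' @param variables variable names to report
#' @param delta per-variable Deming error-variance ratio; single value
#'   recycled (default 1)
#' @return data.frame, one row per variable
#' @export
comparison_table <- function(pairs,
                             variables = c("ph_insitu", "ph_25c", "pco2",
                                           "dic", "ta", "oxygen", "nitrate",
                                           "temp", "sal"),
                             delta = 1) {
  delta <- rep_len(delta, length(variables))
  rows <- lapply(seq_along(variables), function(i) {
    v <- variables[i]
    fv <- pairs[[paste0(v, "_f")]]
    sv <- pairs[[paste0(v, "_s")]]
    if (is.null(fv) || is.null(sv)) return(NULL)
    ok <- is.finite(fv) & is.finite(sv)
    if (sum(ok) < 3) {
      warning("comparison_table: fewer than 3 pairs for ", v, ", omitted")
      return(NULL)
    }
    fit <- deming_fit(sv[ok], fv[ok], delta = delta[i])
    data.frame(variable = v, n = fit$n, slope = fit$slope,
               slope_se = fit$slope_se, s_est = fit$s_est,
               mean_diff = mean(fv[ok] - sv[ok]),
               rel_diff_pct = mean((fv[ok] - sv[ok]) / sv[ok]) * 100,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
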