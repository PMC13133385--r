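# Comparison statistics: Deming regression, deviation degree, depth bins,
# year-difference correlation, Monte Carlo propagation, flux scaling.

test_that("Deming regression is exact on noiseless lines", {
  x <- seq(0, 10, 0.5)
  for (d in c(0.1, 1, 10)) {
    f <- deming_fit(x, 2 * x + 1, delta = d)
    expect_equal(f$slope, 2, tolerance = 1e-10)
    expect_equal(f$intercept, 1, tolerance = 1e-10)
    expect_equal(f$s_est, 0, tolerance = 1e-8)
  }
})

test_that("Deming limits recover the two OLS forms", {
  set.seed(11)
  x <- rnorm(60)
  y <- 1.4 * x + rnorm(60, 0, 0.6)
  ols_yx <- unname(coef(lm(y ~ x))[2])
  ols_xy_inv <- 1 / unname(coef(lm(x ~ y))[2])
  expect_equal(deming_fit(x, y, delta = 1e12)$slope, ols_yx,
               tolerance = 1e-8)
  expect_equal(deming_fit(x, y, delta = 1e-12)$slope, ols_xy_inv,
               tolerance = 1e-8)
})

test_that("Deming recovers a known slope under errors in both variables", {
  set.seed(3)
  truth <- runif(500, 0, 10)
  x <- truth + rnorm(500, 0, 0.8)
  y <- 1.5 * truth + rnorm(500, 0, 0.8)
  f <- deming_fit(x, y, delta = 1)
  expect_lt(abs(f$slope - 1.5), 3 * f$slope_se)
  # OLS on the same data is attenuated below the truth
  expect_lt(unname(coef(lm(y ~ x))[2]), f$slope)
})

test_that("deviation degree matches its definition, not the pooled SD", {
  set.seed(5)
  f <- rnorm(40, 1, 3)
  s <- rnorm(60, 0, 4)
  r <- deviation_degree(f, s)
  expect_equal(r$dd, (mean(f) - mean(s)) / sqrt(sd(f)^2 + sd(s)^2))
  expect_equal(r$se, sqrt(100 / 2400 + r$dd^2 / 200))
  # antisymmetry under group swap
  expect_equal(deviation_degree(s, f)$dd, -r$dd)
  # direct example: mean difference 1, SDs 3 and 4 -> 1/5
  m <- 1 + c(-3, 3) / sqrt(2)  # sd 3, mean 1
  n <- c(-4, 4) / sqrt(2)      # sd 4, mean 0
  expect_equal(deviation_degree(m, n)$dd, 0.2)
  expect_error(deviation_degree(c(1, 1), c(1, 1)), "zero")
})

test_that("depth bins are half-open hundred-metre intervals", {
  pairs <- data.frame(float_depth = c(250, 250, 300, 399.9),
                      ph_insitu_f = c(7.9, 7.9, 7.8, 7.8),
                      ph_insitu_s = c(7.895, 7.895, 7.81, 7.79),
                      d_ph_insitu = c(0.005, 0.005, -0.01, 0.01))
  b <- depth_binned_profiles(pairs, "ph_insitu")
  expect_equal(b$depth_min, c(200, 300))
  # a pair at exactly 300 m falls in [300, 400)
  expect_equal(b$n, c(2, 2))
  expect_equal(b$mean_diff, c(0.005, 0))
  expect_equal(b$sd_diff[1], 0)
})

test_that("a step bias profile is reproduced by the bin means", {
  ds <- cached_dataset("step", quiet_config(
    seed = 9, bias = c(surface = 0, mid = -0.0213, deep = 0)))
  fl <- float_pco2(ds$float, apply_eq1 = FALSE)
  pairs <- match_float_ship(fl, ship_carbonate_derivations(ds$ship))
  b <- depth_binned_profiles(pairs, "ph_insitu")
  mid <- b$depth_min >= 200 & b$depth_max <= 1500
  deep <- b$depth_min >= 1500
  expect_equal(b$mean_diff[mid], rep(-0.0213, sum(mid)), tolerance = 1e-6)
  expect_equal(b$mean_diff[deep], rep(0, sum(deep)), tolerance = 1e-6)
})

test_that("year-difference correlation matches OLS and a permutation null", {
  pairs <- data.frame(year_diff = rep(1:10, 10))
  pairs$d_pco2 <- 2 * pairs$year_diff
  r <- year_difference_correlation(pairs, "pco2")
  expect_equal(r$slope, 2, tolerance = 1e-10)
  expect_equal(r$r, 1, tolerance = 1e-10)
  # null case with a permutation oracle for the p-value
  set.seed(21)
  pairs$d_pco2 <- rnorm(100)
  r0 <- year_difference_correlation(pairs, "pco2")
  expect_lt(abs(r0$slope), 0.2)
  obs <- abs(cor(pairs$year_diff, pairs$d_pco2))
  perm <- replicate(4000, abs(cor(pairs$year_diff, sample(pairs$d_pco2))))
  expect_lt(abs(r0$p - mean(perm >= obs)), 0.02)
  expect_error(year_difference_correlation(
    data.frame(year_diff = rep(3, 5), d_pco2 = rnorm(5)), "pco2"),
    "constant")
})

test_that("Monte Carlo mean-difference propagation behaves analytically", {
  # degenerate case: zero SDs give exactly the mean offset every rep
  r0 <- monte_carlo_delta(sd_f = 0, sd_s = 0, reps = 10, seed = 1)
  expect_equal(r0$mean_diffs, rep(17, 10))
  expect_equal(r0$half_width, 0)
  # defaults: half-width near 1.96 sqrt((11^2+12^2)/724)
  r <- monte_carlo_delta(seed = 4)
  expect_equal(r$mean, 17, tolerance = 0.1)
  expect_equal(r$half_width, 1.1858, tolerance = 0.1)
  # convergence of the half-width to the analytic value at large reps
  rbig <- monte_carlo_delta(reps = 1e5, seed = 8)
  expect_lt(abs(rbig$half_width - 1.1858) / 1.1858, 0.03)
})

test_that("flux scaling reproduces the published endpoints", {
  expect_equal(flux_scaling(0), 0.35)
  expect_equal(flux_scaling(12), -0.28)
  expect_equal(flux_scaling(18), -0.595)
  expect_equal(flux_scaling(4) - flux_scaling(0), -0.21)
})

test_that("the comparison table is ideal on zero-bias zero-noise data", {
  ds <- cached_dataset("quiet", quiet_config())
  fl <- float_pco2(ds$float, apply_eq1 = FALSE)
  pairs <- match_float_ship(fl, ship_carbonate_derivations(ds$ship))
  # without mesoscale variability regressions are degenerate; means remain
  expect_lt(abs(mean(pairs$d_temp)), 1e-5)
  expect_lt(abs(mean(pairs$d_sal)), 1e-9)
  expect_equal(mean(pairs$d_ph_insitu), 0, tolerance = 1e-6)
  expect_equal(mean(pairs$d_pco2), 0, tolerance = 1e-3)
  # with variability, slopes sit near 1 and mean differences near 0
  ds2 <- cached_dataset("smallq", small_config(
    seed = 13, bias = c(surface = 0, mid = 0, deep = 0)))
  tab <- comparison_table(run_mini_pairs(ds2))
  expect_true(all(c("temp", "sal", "oxygen", "pco2") %in% tab$variable))
  t_row <- tab[tab$variable == "temp", ]
  expect_equal(t_row$slope, 1, tolerance = 0.05)
  expect_lt(abs(t_row$rel_diff_pct), 0.1)
  s_row <- tab[tab$variable == "sal", ]
  expect_equal(round(s_row$rel_diff_pct, 2), 0)
  ph_row <- tab[tab$variable == "ph_insitu", ]
  expect_lt(abs(ph_row$mean_diff), 0.003)
})
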