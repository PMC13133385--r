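# Synthetic generator: determinism, internal consistency, injected-bias
# bookkeeping and the crossover reference algorithm.

test_that("configuration rejects impossible study conditions", {
  expect_error(synth_config(n_float = 0), "zero profiles")
  expect_error(synth_config(region = list(lat = c(-50, -50), lon = c(0, 10))),
               "empty region")
  expect_error(synth_config(region = list(lat = c(-30, -20), lon = c(0, 10))),
               "south of 35")
  expect_error(synth_config(grid_noise = -1), "noise")
})

test_that("the same seed reproduces byte-identical CSV output", {
  cfg <- small_config(seed = 31)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  dir1 <- tempfile(); dir2 <- tempfile()
  write_synthetic_csv(d1, dir1)
  write_synthetic_csv(d2, dir2)
  for (f in c("ship.csv", "float.csv", "truth.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  g1 <- generate_surface_grid(d1)
  g2 <- generate_surface_grid(d2)
  expect_identical(g1, g2)
})

test_that("ship (DIC, TA) -> pH reproduces the written ship pH", {
  ds <- cached_dataset("small", small_config())
  s <- ds$ship[seq(1, nrow(ds$ship), by = 17), ]
  ph <- carb_solve(dic = s$dic, ta = s$ta, temp = s$temp, sal = s$sal,
                   pres = s$pressure, silicate = s$silicate,
                   phosphate = s$phosphate)$ph
  expect_lt(max(abs(ph - s$ph_insitu)), 1e-6)
})

test_that("zero bias and zero noise give identical matched platforms", {
  ds <- cached_dataset("quiet", quiet_config())
  fl <- float_pco2(ds$float, apply_eq1 = FALSE)
  pairs <- match_float_ship(fl, ship_carbonate_derivations(ds$ship))
  expect_gt(nrow(pairs), 0)
  # co-located platforms share a water column; the only remaining
  # difference is the latitude dependence of the depth-pressure relation,
  # well below any sensor resolution
  for (v in c("d_temp", "d_sal", "d_oxygen", "d_nitrate", "d_ta",
              "d_ph_insitu")) {
    expect_lt(max(abs(pairs[[v]])), 1e-4)
  }
  expect_lt(max(abs(pairs$d_pco2)), 0.01)
})

test_that("an injected mid-depth bias appears exactly in the deltas", {
  ds <- cached_dataset("step", quiet_config(
    seed = 9, bias = c(surface = 0, mid = -0.0213, deep = 0)))
  fl <- float_pco2(ds$float, apply_eq1 = FALSE)
  pairs <- match_float_ship(fl, ship_carbonate_derivations(ds$ship))
  mid <- pairs$float_depth >= 200 & pairs$float_depth < 1500
  expect_equal(mean(pairs$d_ph_insitu[mid]), -0.0213, tolerance = 1e-6)
  expect_equal(mean(abs(pairs$d_ph_insitu[!mid & pairs$float_depth >= 1500])),
               0, tolerance = 1e-6)
  # truth table records the bias actually applied
  trf <- ds$truth[ds$truth$platform == "float", ]
  expect_true(all(trf$bias_ph[trf$depth >= 200 & trf$depth < 1500] == -0.0213))
  expect_true(all(trf$bias_ph[trf$depth < 200 | trf$depth >= 1500] == 0))
  tr_ship <- ds$truth[ds$truth$platform == "ship", ]
  expect_true(all(tr_ship$bias_ph == 0))
})

test_that("generated deep water is old enough to pass the screen", {
  ds <- cached_dataset("small", small_config())
  tr <- ds$truth
  expect_true(all(tr$canth_true[tr$depth > 1500] < 10))
  expect_lt(max(tr$canth_true[tr$depth >= 1500]), 1)
  # anthropogenic carbon decays monotonically with depth
  one <- tr[tr$profile_id == tr$profile_id[1], ]
  expect_true(all(diff(one$canth_true) < 0))
})

test_that("the reference algorithm reproduces deep pH and ignores the surface", {
  # construction check on a noise-free, jitter-free ocean
  ds <- cached_dataset("quiet", quiet_config())
  ref <- generate_reference_ph_algorithm(ds$ship)
  deep <- ds$ship[ds$ship$depth == 1500, ]
  tr <- ds$truth[ds$truth$platform == "ship" & ds$truth$depth == 1500, ]
  pred <- ref(deep$temp, deep$sal, deep$pressure, deep$oxygen)
  expect_lt(max(abs(pred - tr$ph_true)), 0.002)
  # under the default study conditions the reference stays unbiased at the
  # anchor depth even with measurement noise and mesoscale variability
  ds2 <- cached_dataset("small", small_config())
  ref2 <- generate_reference_ph_algorithm(ds2$ship)
  deep2 <- ds2$ship[ds2$ship$depth == 1500, ]
  tr2 <- ds2$truth[ds2$truth$platform == "ship" & ds2$truth$depth == 1500, ]
  err <- ref2(deep2$temp, deep2$sal, deep2$pressure, deep2$oxygen) - tr2$ph_true
  expect_lt(abs(mean(err)), 0.002)
  # a float profile with an injected deep offset is seen by the reference:
  # measured minus expected equals the offset
  fl <- ds$float[ds$float$profile_id == "F0001", ]
  fl$ph_insitu <- fl$ph_insitu - 0.02
  at <- fl[fl$depth == 1500, ]
  expect_lt(abs(at$ph_insitu - ref(at$temp, at$sal, at$pressure, at$oxygen) -
                  (-0.02)), 0.002)
  # independent of surface values: perturbing surface layers changes nothing
  ship_pert <- ds$ship
  surf <- ship_pert$depth < 200
  ship_pert$ph_insitu[surf] <- ship_pert$ph_insitu[surf] + 0.5
  ref_pert <- generate_reference_ph_algorithm(ship_pert)
  expect_equal(ref_pert(at$temp, at$sal, at$pressure, at$oxygen),
               ref(at$temp, at$sal, at$pressure, at$oxygen))
})

test_that("the surface grid is cell-per-month bookkeeping with known truth", {
  ds <- cached_dataset("quiet", quiet_config())
  g <- generate_surface_grid(ds, noise_sd = 0)
  expect_true(all(g$month %in% 1:12))
  expect_false(anyDuplicated(paste(g$lat, g$lon, g$year, g$month)) > 0)
  # zero noise: cell pCO2 equals a truth surface pCO2 of that month's floats
  tr <- ds$truth[ds$truth$platform == "float" & ds$truth$depth < 5, ]
  expect_true(all(g$pco2 %in% tr$pco2_true))
  # cells lie on 1-degree centers
  expect_true(all(g$lat %% 1 == 0.5 & g$lon %% 1 == 0.5))
})
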