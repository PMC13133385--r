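# Anthropogenic-carbon back-calculations and the unacidified-water screen.

test_that("preformed TA is the exact linear form", {
  # 378.1 + 55.22*34.7 + 0.0716*540 - 1.236*2
  expect_equal(preformed_ta(34.7, 540, 2), 2330.426, tolerance = 1e-9)
  expect_equal(preformed_ta(35.7, 540, 2) - preformed_ta(34.7, 540, 2),
               55.22)
  expect_equal(preformed_ta(34.7, 540, 3) - preformed_ta(34.7, 540, 2),
               -1.236)
  expect_equal(po_tracer(300, 2), 640)
})

test_that("biological DIC change evaluates the printed ratios exactly", {
  expect_equal(delta_c_bio(250, 250, 2330, 2330, 0), 0)
  # AOU term alone: O2 - O2sat = -17 gives 11.7 + 0.8 = 12.5
  expect_equal(delta_c_bio(233, 250, 2330, 2330, 0), 12.5)
  # N* anomaly term alone: -106/104 * 1.04 = -1.06
  expect_equal(delta_c_bio(250, 250, 2330, 2330, 1.04), -1.06)
})

test_that("delta-C* components assemble per the back-calculation identity", {
  r <- canth_delta_c_star(dic = 2250, ta = 2350, oxygen = 200, nitrate = 33,
                          phosphate = 33 / 16, silicate = 82.5,
                          sal = 34.72, theta = 1.5)
  # re-solving pCO2 from (C_280, TA0) at preformed conditions returns 280
  back <- carb_solve(dic = r$c_280, ta = r$ta0, temp = 1.5, sal = 34.72,
                     pres = 0, silicate = 82.5, phosphate = 33 / 16)
  expect_equal(back$pco2, 280, tolerance = 0.01)
  expect_equal(r$canth, r$delta_c_star - r$delta_c_dis)
  # null case: measured DIC equal to the preindustrial construction
  r0 <- canth_delta_c_star(dic = r$c_280 + r$delta_c_bio, ta = 2350,
                           oxygen = 200, nitrate = 33, phosphate = 33 / 16,
                           silicate = 82.5, sal = 34.72, theta = 1.5)
  expect_equal(r0$canth, 0, tolerance = 1e-6)
})

test_that("TrOCA formulas evaluate exactly", {
  r <- canth_troca(oxygen = 200, dic = 2250, ta = 2350, theta = 2)
  expect_equal(r$troca, 1574.925)  # 200 + 1.279*(2250 - 1175)
  expect_equal(r$troca0, 1552.84, tolerance = 0.05)
  # TrOCA equal to its preindustrial reference implies zero C_anth
  r2 <- canth_troca(oxygen = r$troca0 - 1.279 * (2250 - 1175),
                    dic = 2250, ta = 2350, theta = 2)
  expect_equal(r2$canth, 0, tolerance = 1e-9)
  expect_error(canth_troca(200, 2250, 0, 2), "positive")
})

test_that("water-mass classification follows the printed envelopes", {
  expect_equal(classify_watermass(2.7, 27.55), "UCDW")
  expect_equal(classify_watermass(1.5, 27.78), "LCDW")
  expect_equal(classify_watermass(2.7, 27.75), "none")  # too dense for UCDW
  expect_equal(classify_watermass(3.2, 27.55), "none")  # too warm
  expect_equal(classify_watermass(2.5, 27.55), "none")  # boundaries strict
  expect_equal(classify_watermass(-0.5, 27.75), "none") # below LCDW range
})

test_that("the three-fold screen is enforced on the ship side", {
  ds <- cached_dataset("small", small_config())
  m <- run_mini_pairs(ds)
  scr <- screen_unacidified(m, canth_max = 10, delta_c_dis = -15)
  expect_gt(nrow(scr), 0)
  expect_true(all(scr$ship_depth > 200))
  expect_true(all(scr$watermass %in% c("UCDW", "LCDW")))
  expect_true(all(scr$canth < 10))
  # screening never uses float-derived carbon: removing float pco2/dic
  # columns leaves the screened set unchanged
  m2 <- m
  m2$pco2_f <- NULL; m2$dic_f <- NULL; m2$d_pco2 <- NULL; m2$d_dic <- NULL
  scr2 <- screen_unacidified(m2, canth_max = 10, delta_c_dis = -15)
  expect_equal(paste(scr2$float_id, scr2$float_depth),
               paste(scr$float_id, scr$float_depth))
})

test_that("ship delta-C* recovers the generated anthropogenic carbon", {
  ds <- cached_dataset("quiet", quiet_config())
  m <- run_mini_pairs(ds)
  scr <- screen_unacidified(m, canth_max = 10, delta_c_dis = -15)
  tr <- ds$truth[ds$truth$platform == "ship", ]
  truth <- tr$canth_true[match(paste(scr$ship_id, scr$ship_depth),
                               paste(tr$profile_id, tr$depth))]
  # noise-free ship data: the back-calculation inverts the construction
  # up to the interpolated disequilibrium near the mixed-layer base
  expect_lt(max(abs(scr$canth - truth)), 2.5)
  # generated deep water is old: truth C_anth < 10 everywhere below 1500 m
  expect_true(all(tr$canth_true[tr$depth > 1500] < 10))
})

test_that("delta-C* and TrOCA agree on screened synthetic levels", {
  ds <- cached_dataset("small", small_config())
  scr <- screen_unacidified(run_mini_pairs(ds), canth_max = 10,
                            delta_c_dis = -15)
  expect_lt(mean(abs(scr$canth - scr$canth_troca)), 10)
})
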