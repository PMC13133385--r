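# Carbonate system solver: agreement with the frozen reference
# implementation, internal consistency, and the published solubility and
# nutrient rules.

test_that("solver matches the reference implementation across the ocean envelope", {
  # 100-state Latin hypercube solved by an independent scipy/brentq
  # implementation of the same constant set (see inst/oracle)
  o <- read.csv(test_path("fixtures", "carbonate_oracle.csv"))
  st <- carb_solve(ph = o$ph, ta = o$ta, temp = o$temp, sal = o$sal,
                   pres = o$pres, silicate = o$silicate,
                   phosphate = o$phosphate)
  expect_lt(max(abs(st$dic - o$dic)), 1)    # umol kg-1
  expect_lt(max(abs(st$pco2 - o$pco2)), 1)  # uatm
  back <- carb_solve(dic = o$dic, ta = o$ta, temp = o$temp, sal = o$sal,
                     pres = o$pres, silicate = o$silicate,
                     phosphate = o$phosphate)
  expect_lt(max(abs(back$ph - o$ph)), 1e-6)
})

test_that("pinned reference states are reproduced", {
  s <- carb_solve(ta = 2350, pco2 = 280, temp = 2, sal = 34.7, pres = 0)
  expect_equal(s$dic, 2159.993264, tolerance = 1e-6)
  expect_equal(s$ph, 8.18191279, tolerance = 1e-7)
  s2 <- carb_solve(dic = 2200, ta = 2350, temp = 25, sal = 35, pres = 0)
  expect_equal(s2$ph, 7.73613702, tolerance = 1e-7)
  expect_equal(s2$pco2, 936.502740, tolerance = 1e-4)
  s3 <- carb_solve(ph = 8.1, ta = 2300, temp = 2, sal = 34, pres = 0,
                   silicate = 50, phosphate = 1.5)
  expect_equal(s3$dic, 2147.832418, tolerance = 1e-5)
  expect_equal(s3$pco2, 340.165504, tolerance = 1e-4)
})

test_that("inverse solves are self-consistent", {
  st <- carb_solve(ph = 7.9, ta = 2320, temp = 4, sal = 34.3, pres = 800,
                   silicate = 40, phosphate = 1.1)
  back <- carb_solve(dic = st$dic, ta = st$ta, temp = 4, sal = 34.3,
                     pres = 800, silicate = 40, phosphate = 1.1)
  expect_equal(back$ph, 7.9, tolerance = 1e-6)
  fromp <- carb_solve(ta = 2320, pco2 = st$pco2, temp = 4, sal = 34.3,
                      pres = 800, silicate = 40, phosphate = 1.1)
  expect_equal(fromp$dic, st$dic, tolerance = 1e-4)
})

test_that("pCO2 decreases with pH at fixed TA", {
  ph <- seq(7.3, 8.3, by = 0.05)
  for (tc in c(-1, 10, 25)) {
    p <- carb_solve(ph = ph, ta = 2350, temp = tc, sal = 34.7, pres = 0)$pco2
    expect_true(all(diff(p) < 0))
  }
})

test_that("Weiss CO2 solubility has the published magnitude and T-dependence", {
  k <- k0_weiss(seq(0, 30, 2), 35)
  expect_true(all(diff(k) < 0))                      # less soluble when warm
  expect_equal(k0_weiss(1, 35), 0.0605, tolerance = 0.002)
  # converting the 0.84 umol kg-1 surface offset reproduces ~14.1 uatm
  expect_equal(0.84 / k0_weiss(1, 35), 14.1, tolerance = 0.05)
  expect_error(k0_weiss(60, 35), "range")
})

test_that("pH condition conversion conserves DIC and round-trips", {
  # identity when input conditions are already 25 C, 0 dbar
  expect_equal(convert_ph_conditions(7.8, 2300, 25, 34.7, 0), 7.8,
               tolerance = 1e-9)
  # cold deep water expressed at 25 C has lower pH (fixed DIC and TA);
  # value pinned by the reference implementation
  ph25 <- convert_ph_conditions(8.05, 2300, 2, 34.7, 1000,
                                silicate = 30, phosphate = 1.2)
  expect_lt(ph25, 8.05)
  expect_equal(ph25, 7.74212957, tolerance = 1e-6)
  # round trip 25 C -> in-situ -> 25 C
  ph_in <- convert_ph_conditions(ph25, 2300, 25, 34.7, 0, silicate = 30,
                                 phosphate = 1.2, temp_out = 2,
                                 pres_out = 1000)
  expect_equal(ph_in, 8.05, tolerance = 1e-6)
})

test_that("Redfield nutrient estimation follows the quoted rule", {
  expect_equal(nutrients_from_nitrate(32, TRUE),
               list(silicate = 80, phosphate = 2))
  expect_equal(nutrients_from_nitrate(0, TRUE),
               list(silicate = 0, phosphate = 0))
  expect_equal(nutrients_from_nitrate(32, FALSE),
               list(silicate = 0, phosphate = 0))
  expect_equal(nutrients_from_nitrate(c(16, NA), c(TRUE, TRUE)),
               list(silicate = c(40, 0), phosphate = c(1, 0)))
})

test_that("degenerate inputs raise informative errors", {
  expect_error(carb_solve(ph = 8, temp = 2, sal = 34.7),
               "exactly two")
  expect_error(carb_solve(ph = 8, dic = 2100, ta = 2300, temp = 2, sal = 34.7),
               "exactly two")
})
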