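# Profile, level, grid and season matching rules.

test_that("haversine distance is exact on the 6371-km sphere", {
  expect_equal(haversine_km(-60, 10, -60, 10), 0)
  expect_equal(haversine_km(-60, 0, -55, 30), haversine_km(-55, 30, -60, 0))
  # 0.225 degrees of latitude = 0.225 * pi/180 * 6371 km
  expect_equal(haversine_km(-60, 0, -60.225, 0), 25.0169,
               tolerance = 1e-3)
})

test_that("profile matching selects the closest cast within 25 km", {
  fl <- toy_float_levels()
  s1 <- toy_ship_levels("S_far")   # offset ~20 km
  s1$lat <- s1$lat + 20 / 111.2
  s2 <- toy_ship_levels("S_near")  # offset ~5 km
  s2$lat <- s2$lat + 5 / 111.2
  m <- match_profiles(fl, rbind(s1, s2))
  expect_equal(m$ship_id, "S_near")
  # beyond the window: no pair
  s3 <- toy_ship_levels("S_out")
  s3$lat <- s3$lat + 26 / 111.2
  expect_equal(nrow(match_profiles(fl, s3)), 0)
})

test_that("equidistant casts break ties by earlier timestamp", {
  fl <- toy_float_levels()
  a <- toy_ship_levels("S_b", date = "2012-01-15")
  b <- toy_ship_levels("S_a", date = "2008-01-15")
  a$lat <- a$lat + 10 / 111.2
  b$lat <- b$lat - 10 / 111.2
  m <- match_profiles(fl, rbind(a, b))
  expect_equal(m$ship_id, "S_a")
})

test_that("level matching windows depend on the float depth", {
  fl <- toy_float_levels(depth = c(150, 500))
  sh <- toy_ship_levels(depth = c(158, 620))
  lm <- match_levels(fl, sh)
  # 150 m float, 158 m ship: within the 10 m shallow window
  expect_equal(lm$float_depth, 150)
  expect_equal(lm$depth_diff, -8)
  # 500 m float, 620 m ship: outside the 100 m deep window -> unmatched
  expect_false(500 %in% lm$float_depth)
  # smallest depth difference wins among in-window candidates
  sh2 <- toy_ship_levels(depth = c(495, 540))
  lm2 <- match_levels(toy_float_levels(depth = 500), sh2)
  expect_equal(lm2$ship_depth, 495)
})

test_that("matched pairs never violate the distance or depth invariants", {
  ds <- cached_dataset("small", small_config())
  fl <- ds$float
  fl$ta <- fl$ta_estimated
  pairs <- match_float_ship(fl, ds$ship)
  expect_gt(nrow(pairs), 0)
  expect_true(all(pairs$distance_km <= 25))
  expect_true(all(abs(pairs$depth_diff) <=
                    ifelse(pairs$float_depth < 200, 10, 100)))
  # co-located floats are constructed within 18 km of a ship site, so at
  # least the constructed fraction of float profiles must be recovered
  n_co <- round(0.8 * ds$config$n_float)
  expect_gte(length(unique(pairs$float_id)), 0.95 * n_co)
})

test_that("grid matching requires same month, same year, 25 km", {
  cells <- data.frame(lat = -60.5, lon = 0.5, year = 2020, month = 1,
                      pco2 = 390)
  fs <- data.frame(profile_id = "F1", lat = -60.55, lon = 0.5, year = 2020,
                   month = 1, pco2 = 400)
  m <- match_float_grid(fs, cells)
  expect_equal(m$d_pco2, 10)
  fs$month <- 2
  expect_equal(nrow(match_float_grid(fs, cells)), 0)
  fs$month <- 1
  fs$lat <- -61.5   # > 25 km from the cell center
  expect_equal(nrow(match_float_grid(fs, cells)), 0)
})

test_that("float surface values use the shallowest level above 5 m", {
  fl <- toy_float_levels(depth = c(4, 150))
  fl$pco2 <- c(401, 500)
  sv <- float_surface_values(fl)
  expect_equal(sv$pco2, 401)
  # a profile whose shallowest level is 6 m has no surface value
  fl2 <- toy_float_levels(id = "F2", depth = c(6, 150))
  fl2$pco2 <- c(402, 500)
  expect_equal(nrow(float_surface_values(fl2)), 0)
})

test_that("austral season filter keeps same-season pairs only", {
  expect_equal(austral_season(c(12, 1, 2)), rep("summer", 3))
  expect_equal(austral_season(c(3, 6, 9)), c("autumn", "winter", "spring"))
  pairs <- data.frame(float_month = c(1, 1, 7), ship_month = c(12, 3, 8))
  kept <- filter_same_season(pairs)
  # Jan/Dec both summer: kept; Jan/Mar crosses seasons: dropped
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$ship_month %in% c(12, 8)))
  # an all-same-month table passes unchanged
  same <- data.frame(float_month = rep(5, 4), ship_month = rep(5, 4))
  expect_equal(filter_same_season(same), same)
})
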