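# Synthetic Southern Ocean float / ship / gridded-surface generator.
#
# The generator emulates the statistical structure the analysis assumes: a
# mixed layer over UCDW and LCDW envelopes, per-variable sensor noise, a
# configurable piecewise-constant float pH bias in depth, and an
# anthropogenic-carbon profile that vanishes in old deep water. Truth DIC
# is constructed through the back-calculation identity
#   DIC = C_280(TA0, theta) + delta-C_bio + delta-C_dis + C_anth(z)
# so that the water column is exactly consistent with the preformed-tracer
# budget and the anthropogenic component is known at every level. Ship
# carbonate variables (pH, pCO2) are solved from the measured (DIC, TA) by
# the carbonate module, making ship profiles internally consistent; float
# pH is truth pH plus the injected bias plus sensor noise.

#' Synthetic dataset configuration
#'
#' Defaults define the reference study conditions: profile counts scaled to
#' desk size, Southern Ocean region south of 35 S, ship sampling 1990-2015
#' and float sampling 2015-2023, water-column anchors inside the published
#' UCDW/LCDW envelopes, a 45 umol kg-1 surface anthropogenic-carbon load
#' decaying with a 300 m e-folding scale (< 1 umol kg-1 below 1500 m), an
#' air-sea disequilibrium of -15 umol kg-1 in the deep water masses, a
#' float pH bias of (-0.015 surface, -0.0213 at 200-1500 m, 0 below
#' 1500 m), and per-variable noise SDs (pH 0.01, O2 3, NO3 0.3, T 0.01,
#' S 0.005, estimated TA 5.6 umol kg-1, gridded pCO2 14 uatm).
#'
#' @param seed integer RNG seed
#' @param n_ship,n_float profile counts
#' @param colocated_frac fraction of float profiles placed within
#'   `colocated_km` of a ship site (sharing its water column, as subsurface
#'   water is assumed time-invariant)
#' @param colocated_km maximum offset of a colocated float from its ship
#'   site, km
#' @param region list(lat = c(min, max), lon = c(min, max)), south of 35 S
#' @param ship_years,float_years sampling year ranges
#' @param depths sampling depth grid, m (shared by both platforms)
#' @param anchors data.frame of water-column anchor values by depth:
#'   columns depth, theta, sal, ta, oxygen, nitrate, dcdis; linearly
#'   interpolated
#' @param canth_surface surface anthropogenic carbon, umol kg-1
#' @param canth_scale e-folding depth of the anthropogenic profile, m
#' @param bias float pH bias: c(surface, mid, deep) applied for depth
#'   < 200, [200, 1500) and >= 1500 m; bands are half-open so the 1500 m
#'   crossover anchor sits in the deep band. The default is a
#'   pressure-independent -0.0213 residual offset above the anchor depth
#'   and none below it
#' @param bias_other named additive float biases for other variables
#'   (default all 0), e.g. c(oxygen = -3)
#' @param noise named float sensor noise SDs
#' @param ship_noise named ship measurement noise SDs
#' @param site_jitter named per-site SDs of anchor perturbations
#'   (mesoscale variability shared by a site's ship and float profiles)
#' @param grid_noise gridded-surface pCO2 noise SD, uatm
#' @param xco2,slp atmospheric CO2 mole fraction (ppm) and sea-level
#'   pressure (atm), either scalars or data.frames (year, month, xco2/slp)
#' @return configuration list of class "synth_config"
#' @export
synth_config <- function(seed = 1,
                         n_ship = 250, n_float = 400,
                         colocated_frac = 0.8, colocated_km = 18,
                         region = list(lat = c(-62, -48), lon = c(-60, -20)),
                         ship_years = 1990:2015, float_years = 2015:2023,
                         depths = c(4, 25, 50, 100, 150, 200, 250, 300, 400,
                                    500, 600, 700, 800, 900, 1000, 1100,
                                    1200, 1300, 1400, 1500, 1600, 1700,
                                    1800, 1900, 2000),
                         anchors = data.frame(
                           depth = c(0, 150, 700, 1800, 2200),
                           theta = c(1.2, 1.2, 2.7, 1.5, 1.45),
                           sal = c(33.9, 34.05, 34.55, 34.72, 34.73),
                           ta = c(2285, 2290, 2335, 2350, 2351),
                           oxygen = c(333.4, 325, 185, 200, 202),
                           nitrate = c(24, 26, 35, 32.5, 32.3),
                           dcdis = c(-5, -5, -15, -15, -15)),
                         canth_surface = 45, canth_scale = 300,
                         bias = c(surface = -0.0213, mid = -0.0213, deep = 0),
                         bias_other = c(oxygen = 0, nitrate = 0,
                                        temp = 0, sal = 0),
                         noise = c(ph = 0.01, oxygen = 3, nitrate = 0.3,
                                   temp = 0.01, sal = 0.005,
                                   ta_estimated = 5.6),
                         ship_noise = c(dic = 2, ta = 2, oxygen = 1,
                                        nitrate = 0.2, temp = 0.002,
                                        sal = 0.002, silicate = 1,
                                        phosphate = 0.02),
                         site_jitter = c(theta = 0.05, sal = 0.01, ta = 1,
                                         oxygen = 5, nitrate = 0.25),
                         grid_noise = 14,
                         xco2 = 400, slp = 0.98) {
  cfg <- list(seed = seed, n_ship = n_ship, n_float = n_float,
              colocated_frac = colocated_frac, colocated_km = colocated_km,
              region = region, ship_years = ship_years,
              float_years = float_years, depths = depths, anchors = anchors,
              canth_surface = canth_surface, canth_scale = canth_scale,
              bias = bias, bias_other = bias_other, noise = noise,
              ship_noise = ship_noise, site_jitter = site_jitter,
              grid_noise = grid_noise, xco2 = xco2, slp = slp)
  if (n_ship < 1 || n_float < 1) stop("synth_config: zero profiles")
  if (diff(region$lat) <= 0 || diff(region$lon) <= 0) {
    stop("synth_config: empty region")
  }
  if (max(region$lat) > -35) stop("synth_config: region must lie south of 35 S")
  if (any(c(noise, ship_noise, grid_noise) < 0)) {
    stop("synth_config: noise SDs must be >= 0")
  }
  class(cfg) <- "synth_config"
  cfg
}

# monthly scalar series as a data.frame covering the given years
.monthly_series <- function(x, years, col) {
  if (is.data.frame(x)) return(x)
  d <- expand.grid(month = 1:12, year = min(years):max(years))
  d[[col]] <- x
  d[, c("year", "month", col)]
}

#' Monthly atmospheric xCO2 / sea-level pressure series from a config
#'
#' @param config synth_config
#' @return list with `xco2` and `slp` data.frames (year, month, value)
#' @export
synth_series <- function(config) {
  years <- range(c(config$ship_years, config$float_years))
  list(xco2 = .monthly_series(config$xco2, years, "xco2"),
       slp = .monthly_series(config$slp, years, "slp"))
}

# Saunders (1981) depth (m) -> pressure (dbar)
depth_to_pressure <- function(depth, lat) {
  c1 <- (5.92 + 5.25 * sin(lat * pi / 180)^2) * 1e-3
  ((1 - c1) - sqrt((1 - c1)^2 - 8.84e-6 * depth)) / 4.42e-6
}

# Piecewise-constant pH bias in depth; bands are half-open so the 1500 m
# crossover anchor lies in the deep band (the residual bias after a
# 1500-m-anchored adjustment is zero at the anchor by construction).
.bias_at <- function(depth, bias) {
  ifelse(depth < 200, bias[["surface"]],
         ifelse(depth < 1500, bias[["mid"]], bias[["deep"]]))
}

# Truth water column at given depths for one site (anchors possibly
# perturbed); returns all truth variables including constructed DIC and
# the solved carbonate state.
.truth_column <- function(depths, anchors, lat, canth_surface, canth_scale) {
  ip <- function(col) stats::approx(anchors$depth, anchors[[col]], depths,
                                    rule = 2)$y
  theta <- ip("theta"); sal <- ip("sal"); ta <- ip("ta")
  oxygen <- ip("oxygen"); nitrate <- ip("nitrate"); dcdis <- ip("dcdis")
  pres <- depth_to_pressure(depths, lat)
  temp <- potential_temperature(sal, theta, 0, pres)  # theta -> in-situ
  silicate <- 2.5 * nitrate
  phosphate <- nitrate / 16
  canth <- canth_surface * exp(-depths / canth_scale)
  po <- po_tracer(oxygen, phosphate)
  ta0 <- preformed_ta(sal, po, theta)
  o2s <- o2_saturation_1atm(theta, sal)
  dcb <- delta_c_bio(oxygen, o2s, ta, ta0, nstar_anom = 0)
  c280 <- carb_solve(ta = ta0, pco2 = 280, temp = theta, sal = sal, pres = 0,
                     silicate = silicate, phosphate = phosphate)$dic
  dic <- c280 + dcb + dcdis + canth
  st <- carb_solve(dic = dic, ta = ta, temp = temp, sal = sal, pres = pres,
                   silicate = silicate, phosphate = phosphate)
  data.frame(depth = depths, pressure = pres, theta = theta, temp = temp,
             sal = sal, ta = ta, oxygen = oxygen, nitrate = nitrate,
             silicate = silicate, phosphate = phosphate, dcdis = dcdis,
             canth = canth, dic = dic, ph = st$ph, pco2 = st$pco2)
}

.rand_date <- function(n, years) {
  sprintf("%d-%02d-15", sample(years, n, replace = TRUE),
          sample(1:12, n, replace = TRUE))
}

# displace (lat, lon) by r km at bearing b
.offset_position <- function(lat, lon, r_km, bearing) {
  dlat <- r_km * cos(bearing) / 111.2
  dlon <- r_km * sin(bearing) / (111.2 * cos(lat * pi / 180))
  list(lat = lat + dlat, lon = lon + dlon)
}

#' Generate a synthetic float-ship dataset with known truth
#'
#' Draws ship sites (one cast per site) and float profiles (a configurable
#' fraction colocated with ship sites within 25 km, sharing the site's
#' water column), builds truth columns, and emits measurement tables in
#' the package's CSV-ready layouts plus a truth record per generated
#' level. Ship pH/pCO2 are solved from the noisy measured (DIC, TA); float
#' pH is truth plus injected bias plus noise. The truth table carries the
#' noise-free float-processing result (crossover + pH-dependent correction
#' + pCO2 solve applied to the biased, noise-free profile) so that
#' recovery of the injected bias can be checked like for like.
#'
#' @param config from [synth_config()]
#' @return list with `ship`, `float` (level tables), `truth` (per-level
#'   truth records), `series` (xCO2/SLP), and `config`
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  rg <- config$region
  ns <- config$n_ship; nf <- config$n_float
  sites <- data.frame(
    site = seq_len(ns),
    lat = stats::runif(ns, rg$lat[1], rg$lat[2]),
    lon = stats::runif(ns, rg$lon[1], rg$lon[2]))
  jit <- config$site_jitter
  jcols <- names(jit)
  jitter_mat <- vapply(jcols, function(v) stats::rnorm(ns, 0, jit[[v]]),
                       numeric(ns))
  site_anchors <- function(s) {
    a <- config$anchors
    for (v in jcols) a[[v]] <- a[[v]] + jitter_mat[s, v]
    a
  }

  ## ship profiles
  ship_dates <- .rand_date(ns, config$ship_years)
  sn <- config$ship_noise
  ship <- do.call(rbind, lapply(seq_len(ns), function(s) {
    tc <- .truth_column(config$depths, site_anchors(s), sites$lat[s],
                        config$canth_surface, config$canth_scale)
    nl <- nrow(tc)
    m <- data.frame(
      profile_id = sprintf("S%04d", s), lat = sites$lat[s],
      lon = sites$lon[s], date = ship_dates[s],
      depth = tc$depth, pressure = tc$pressure,
      temp = tc$temp + stats::rnorm(nl, 0, sn[["temp"]]),
      sal = tc$sal + stats::rnorm(nl, 0, sn[["sal"]]),
      oxygen = tc$oxygen + stats::rnorm(nl, 0, sn[["oxygen"]]),
      nitrate = tc$nitrate + stats::rnorm(nl, 0, sn[["nitrate"]]),
      silicate = tc$silicate + stats::rnorm(nl, 0, sn[["silicate"]]),
      phosphate = tc$phosphate + stats::rnorm(nl, 0, sn[["phosphate"]]),
      ta = tc$ta + stats::rnorm(nl, 0, sn[["ta"]]),
      dic = tc$dic + stats::rnorm(nl, 0, sn[["dic"]]),
      stringsAsFactors = FALSE)
    attr(m, "truth") <- tc
    m
  }))
  st <- carb_solve(dic = ship$dic, ta = ship$ta, temp = ship$temp,
                   sal = ship$sal, pres = ship$pressure,
                   silicate = ship$silicate, phosphate = ship$phosphate)
  ship$ph_insitu <- st$ph
  ship$pco2 <- st$pco2
  ship$ph_25c <- carb_solve(dic = ship$dic, ta = ship$ta, temp = 25,
                            sal = ship$sal, pres = 0,
                            silicate = ship$silicate,
                            phosphate = ship$phosphate)$ph
  for (v in SHIP_FLAGGED_VARS) ship[[paste0("f_", v)]] <- 1L
  ship$platform <- "ship"

  ## float profiles
  co <- stats::runif(nf) < config$colocated_frac
  fsite <- ifelse(co, sample(ns, nf, replace = TRUE), NA_integer_)
  r <- stats::runif(nf, 0, config$colocated_km)
  b <- stats::runif(nf, 0, 2 * pi)
  flat <- ifelse(co, NA_real_, stats::runif(nf, rg$lat[1], rg$lat[2]))
  flon <- ifelse(co, NA_real_, stats::runif(nf, rg$lon[1], rg$lon[2]))
  pos <- .offset_position(sites$lat[ifelse(is.na(fsite), 1, fsite)],
                          sites$lon[ifelse(is.na(fsite), 1, fsite)], r, b)
  flat[co] <- pos$lat[co]
  flon[co] <- pos$lon[co]
  # non-colocated floats get their own water-column jitter
  own_jit <- vapply(jcols, function(v) stats::rnorm(nf, 0, jit[[v]]),
                    numeric(nf))
  float_dates <- .rand_date(nf, config$float_years)
  nz <- config$noise
  bo <- config$bias_other
  flt <- vector("list", nf)
  cln <- vector("list", nf)
  truth_f <- vector("list", nf)
  for (i in seq_len(nf)) {
    a <- if (co[i]) site_anchors(fsite[i]) else {
      a0 <- config$anchors
      for (v in jcols) a0[[v]] <- a0[[v]] + own_jit[i, v]
      a0
    }
    tc <- .truth_column(config$depths, a, flat[i],
                        config$canth_surface, config$canth_scale)
    nl <- nrow(tc)
    bias_ph <- .bias_at(tc$depth, config$bias)
    base <- data.frame(
      profile_id = sprintf("F%04d", i), lat = flat[i], lon = flon[i],
      date = float_dates[i], depth = tc$depth, pressure = tc$pressure,
      stringsAsFactors = FALSE)
    flt[[i]] <- cbind(base, data.frame(
      temp = tc$temp + bo[["temp"]] + stats::rnorm(nl, 0, nz[["temp"]]),
      sal = tc$sal + bo[["sal"]] + stats::rnorm(nl, 0, nz[["sal"]]),
      oxygen = tc$oxygen + bo[["oxygen"]] + stats::rnorm(nl, 0, nz[["oxygen"]]),
      nitrate = tc$nitrate + bo[["nitrate"]] +
        stats::rnorm(nl, 0, nz[["nitrate"]]),
      ph_insitu = tc$ph + bias_ph + stats::rnorm(nl, 0, nz[["ph"]]),
      ta_estimated = tc$ta + stats::rnorm(nl, 0, nz[["ta_estimated"]])))
    # noise-free twin used to define the effectively injected pCO2 bias
    cln[[i]] <- cbind(base, data.frame(
      temp = tc$temp, sal = tc$sal, oxygen = tc$oxygen, nitrate = tc$nitrate,
      ph_insitu = tc$ph + bias_ph, ta_estimated = tc$ta))
    truth_f[[i]] <- data.frame(
      profile_id = sprintf("F%04d", i), platform = "float",
      depth = tc$depth, ph_true = tc$ph, dic_true = tc$dic,
      pco2_true = tc$pco2, canth_true = tc$canth, bias_ph = bias_ph,
      stringsAsFactors = FALSE)
  }
  float <- do.call(rbind, flt)
  for (v in FLOAT_FLAGGED_VARS) float[[paste0("qc_", v)]] <- 0L
  float$platform <- "float"

  ## truth records, including the noise-free processed float pCO2:
  ## an ideal crossover (offset exactly minus the deep injected bias)
  ## followed by the pH-dependent correction and the pCO2 solve
  truth <- do.call(rbind, truth_f)
  clean <- do.call(rbind, cln)
  clean$ph_insitu <- clean$ph_insitu - config$bias[["deep"]]
  clean <- float_pco2(clean, apply_eq1 = TRUE)
  ckey <- paste(clean$profile_id, clean$depth)
  tkey <- paste(truth$profile_id, truth$depth)
  truth$pco2_biased <- clean$pco2[match(tkey, ckey)]
  truth$dic_biased <- clean$dic[match(tkey, ckey)]

  truth_ship <- do.call(rbind, lapply(seq_len(ns), function(s) {
    tc <- .truth_column(config$depths, site_anchors(s), sites$lat[s],
                        config$canth_surface, config$canth_scale)
    data.frame(profile_id = sprintf("S%04d", s), platform = "ship",
               depth = tc$depth, ph_true = tc$ph, dic_true = tc$dic,
               pco2_true = tc$pco2, canth_true = tc$canth, bias_ph = 0,
               pco2_biased = NA_real_, dic_biased = NA_real_,
               stringsAsFactors = FALSE)
  }))
  truth <- rbind(truth, truth_ship)

  list(ship = ship, float = float, truth = truth,
       series = synth_series(config), config = config)
}

#' Reference deep-pH algorithm from ship data
#'
#' Fits the empirical crossover reference: a linear model of ship
#' pH(in-situ) on T, S, P and O2, trained on ship levels between 1000 and
#' 2000 m, mirroring the float DMQC practice of estimating the expected
#' deep pH from shipboard bottle data. The returned estimator is
#' independent of surface values by construction of its training window.
#'
#' @param ship ship level table
#' @param depth_range training window, m (default c(1000, 2000))
#' @return function(temp, sal, pres, oxygen) -> expected pH(in-situ)
#' @export
generate_reference_ph_algorithm <- function(ship, depth_range = c(1000, 2000)) {
  d <- ship[ship$depth >= depth_range[1] & ship$depth <= depth_range[2], ]
  if (nrow(d) < 10) stop("too few deep ship levels to fit the reference")
  # quadratic pressure term: the deep pH profile is not linear in depth,
  # and the reference must be unbiased at the 1500 m anchor
  fit <- stats::lm(ph_insitu ~ temp + sal + pressure + I(pressure^2) + oxygen,
                   data = d)
  cf <- stats::coef(fit)
  function(temp, sal, pres, oxygen) {
    unname(cf[1] + cf["temp"] * temp + cf["sal"] * sal +
             cf["pressure"] * pres + cf["I(pressure^2)"] * pres^2 +
             cf["oxygen"] * oxygen)
  }
}

#' Generate a gridded monthly surface pCO2 product
#'
#' Creates 1-degree monthly cells covering the float surface positions;
#' each cell's pCO2 is the truth surface pCO2 of the first float profile
#' falling in it that month plus Gaussian noise (default SD 14 uatm).
#'
#' @param dataset from [generate_dataset()]
#' @param noise_sd cell noise SD, uatm (default from the config)
#' @return data.frame of cells (lat, lon, year, month, pco2)
#' @export
generate_surface_grid <- function(dataset, noise_sd = NULL) {
  cfg <- dataset$config
  if (is.null(noise_sd)) noise_sd <- cfg$grid_noise
  set.seed(cfg$seed + 1L)
  fl <- dataset$float
  if (nrow(fl) == 0) {
    return(data.frame(lat = numeric(0), lon = numeric(0),
                      year = integer(0), month = integer(0),
                      pco2 = numeric(0)))
  }
  surf <- fl[fl$depth == min(fl$depth), ]
  tr <- dataset$truth
  key <- paste(tr$profile_id, tr$depth)
  surf$pco2_true <- tr$pco2_true[match(paste(surf$profile_id, surf$depth), key)]
  surf$year <- as.integer(format(as.Date(surf$date), "%Y"))
  surf$month <- as.integer(format(as.Date(surf$date), "%m"))
  surf$clat <- floor(surf$lat) + 0.5
  surf$clon <- floor(surf$lon) + 0.5
  cellkey <- paste(surf$clat, surf$clon, surf$year, surf$month)
  first <- !duplicated(cellkey)
  cells <- data.frame(lat = surf$clat[first], lon = surf$clon[first],
                      year = surf$year[first], month = surf$month[first],
                      pco2 = surf$pco2_true[first] +
                        stats::rnorm(sum(first), 0, noise_sd))
  cells
}

#' Write a generated dataset to CSV files
#'
#' @param dataset from [generate_dataset()]
#' @param dir output directory
#' @return invisibly, the paths written
#' @export
write_synthetic_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- file.path(dir, "ship.csv")
  pf <- file.path(dir, "float.csv")
  pt <- file.path(dir, "truth.csv")
  write_profile_table(dataset$ship, ps)
  write_profile_table(dataset$float, pf)
  utils::write.csv(dataset$truth, pt, row.names = FALSE, quote = FALSE)
  invisible(c(ps, pf, pt))
}
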