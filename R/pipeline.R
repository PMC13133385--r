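# End-to-end orchestration: synth -> adjust -> match -> screen -> compare
# -> CORS -> grid -> Monte Carlo -> flux, with a machine-readable manifest.

#' Derive ship carbonate variables from measured DIC and TA
#'
#' Ship pCO2 (and pH at 25 C, 0 dbar, when absent) is calculated from the
#' measured DIC and TA with the package's carbonate solver, using measured
#' silicate and phosphate.
#'
#' @param ship ship level table
#' @return `ship` with pco2 (and ph_25c) columns present
#' @export
ship_carbonate_derivations <- function(ship) {
  sil <- ifelse(is.finite(ship$silicate), ship$silicate, 0)
  pho <- ifelse(is.finite(ship$phosphate), ship$phosphate, 0)
  if (!"pco2" %in% names(ship)) {
    ship$pco2 <- carb_solve(dic = ship$dic, ta = ship$ta, temp = ship$temp,
                            sal = ship$sal, pres = ship$pressure,
                            silicate = sil, phosphate = pho)$pco2
  }
  if (!"ph_25c" %in% names(ship) || all(is.na(ship$ph_25c))) {
    ship$ph_25c <- carb_solve(dic = ship$dic, ta = ship$ta, temp = 25,
                              sal = ship$sal, pres = 0,
                              silicate = sil, phosphate = pho)$ph
  }
  ship
}

.surface_records <- function(levels, platform, max_depth = 5) {
  s <- levels[levels$depth < max_depth & is.finite(levels$pco2), , drop = FALSE]
  s <- s[order(s$profile_id, s$depth), ]
  s <- s[!duplicated(s$profile_id), ]
  data.frame(platform = platform, profile_id = s$profile_id,
             temp = s$temp, sal = s$sal, oxygen = s$oxygen, pco2 = s$pco2,
             year = as.integer(format(as.Date(s$date), "%Y")),
             month = as.integer(format(as.Date(s$date), "%m")),
             stringsAsFactors = FALSE)
}

#' Run the full bias-diagnosis pipeline
#'
#' Generates (or takes) a synthetic dataset, applies the float processing
#' chain (deep crossover adjustment against a ship-trained reference, then
#' the pH-dependent correction and pCO2/DIC derivation), matches float and
#' ship profiles and levels, screens for unacidified Circumpolar Deep
#' Water, and computes the comparison statistics: the per-variable Deming
#' table, 100-m depth-binned differences and deviation degrees, the
#' year-difference correlation, the same-season sensitivity table, the
#' CORS surface analysis with its implied surface pCO2 bias, the
#' float-gridded-surface comparison, the Monte Carlo uncertainty bound and
#' the implied flux range.
#'
#' @param config [synth_config()]; ignored if `dataset` is supplied
#' @param dataset optional pre-built dataset (as from [generate_dataset()])
#' @param out_dir optional output directory for TSV tables and
#'   manifest.json
#' @param canth_max anthropogenic-carbon screening threshold, umol kg-1
#' @param delta_c_dis air-sea disequilibrium used in the delta-C* estimate,
#'   umol kg-1 (default -15, a representative Circumpolar Deep Water value)
#' @return manifest list with record counts per stage and all headline
#'   metrics
#' @export
run_pipeline <- function(config = synth_config(), dataset = NULL,
                         out_dir = NULL, canth_max = 10, delta_c_dis = -15) {
  if (is.null(dataset)) dataset <- generate_dataset(config)
  config <- dataset$config
  counts <- list(ship_levels = nrow(dataset$ship),
                 float_levels = nrow(dataset$float))

  grid <- generate_surface_grid(dataset)
  reference <- generate_reference_ph_algorithm(dataset$ship)
  ship <- ship_carbonate_derivations(dataset$ship)

  adj <- crossover_adjust(dataset$float, reference)
  counts$float_profiles_unadjustable <- sum(!adj$crossover$adjustable)
  fl <- float_pco2(adj$floats)
  counts$float_levels_adjusted <- nrow(fl)

  if (nrow(fl) == 0 || nrow(ship) == 0) {
    stop("match stage: no float or ship records to match")
  }
  pairs <- match_float_ship(fl, ship)
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop("match stage: no float-ship pairs within the match windows")
  }
  counts$matched_pairs <- nrow(pairs)
  counts$matched_profiles <- length(unique(pairs$float_id))

  screened <- screen_unacidified(pairs, canth_max = canth_max,
                                 delta_c_dis = delta_c_dis)
  counts$screened_pairs <- nrow(screened)
  counts$unscreened_pairs <- nrow(pairs) - nrow(screened)

  table1 <- comparison_table(screened)
  bins_ph <- depth_binned_profiles(screened, "ph_insitu")
  bins_pco2 <- depth_binned_profiles(screened, "pco2")
  ydc <- year_difference_correlation(screened, "pco2")
  season <- filter_same_season(screened)
  counts$same_season_pairs <- nrow(season)
  table1_season <- if (nrow(season) >= 3) comparison_table(season) else NULL

  ## CORS surface analysis
  surf <- rbind(.surface_records(fl, "float"),
                .surface_records(ship, "ship"))
  counts$surface_records <- nrow(surf)
  states <- surface_gas_state(surf, dataset$series$xco2, dataset$series$slp)
  cfit <- cors_fit(states)
  cors_bias <- offset_to_pco2_bias(cfit$intercept_offset)

  ## gridded-surface comparison
  fs <- float_surface_values(fl)
  gm <- match_float_grid(fs, grid)
  counts$grid_matches <- nrow(gm)
  grid_mean_diff <- if (nrow(gm)) mean(gm$d_pco2) else NA_real_

  mc <- monte_carlo_delta(seed = config$seed + 2L)

  mid <- screened$float_depth >= 200 & screened$float_depth < 1500
  deep <- screened$float_depth >= 1500
  metrics <- list(
    mean_dph_200_1500 = mean(screened$d_ph_insitu[mid]),
    mean_dph_below_1500 = mean(screened$d_ph_insitu[deep]),
    mean_dpco2_200_1500 = mean(screened$d_pco2[mid]),
    mean_dpco2_below_1500 = mean(screened$d_pco2[deep]),
    canth_method_mad = mean(abs(screened$canth - screened$canth_troca)),
    cors_intercept_float = cfit$fits$intercept[cfit$fits$platform == "float"],
    cors_intercept_ship = cfit$fits$intercept[cfit$fits$platform == "ship"],
    cors_offset = cfit$intercept_offset,
    cors_implied_surface_bias = cors_bias,
    grid_mean_dpco2 = grid_mean_diff,
    mc_half_width = mc$half_width,
    year_diff_slope = ydc$slope, year_diff_r = ydc$r, year_diff_p = ydc$p,
    flux_unbiased = flux_scaling(0),
    flux_at_cors_bias = flux_scaling(cors_bias),
    flux_at_12 = flux_scaling(12), flux_at_18 = flux_scaling(18))

  cfg_yaml <- yaml::as.yaml(config[setdiff(names(config), "anchors")])
  tf <- tempfile(); writeLines(c(cfg_yaml,
                                 utils::capture.output(print(config$anchors))),
                               tf)
  manifest <- list(seed = config$seed,
                   config_hash = unname(tools::md5sum(tf)),
                   counts = counts, metrics = metrics)
  unlink(tf)

  if (!is.null(out_dir)) {
    tables <- list(comparison = table1, depth_bins_ph = bins_ph,
                   depth_bins_pco2 = bins_pco2, cors_fits = cfit$fits,
                   grid_matches = gm)
    if (!is.null(table1_season)) tables$comparison_same_season <- table1_season
    write_report(tables, metrics, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest$tables <- list(comparison = table1, depth_bins_ph = bins_ph,
                          depth_bins_pco2 = bins_pco2, cors = cfit$fits,
                          comparison_same_season = table1_season)
  invisible(manifest)
}
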