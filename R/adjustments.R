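# Float pH adjustment procedures: the deep (1500 m) crossover offset
# against an empirical reference algorithm, and the pH-dependent correction
# applied only when computing pCO2 from float pH and estimated TA.

#' pH-dependent correction for float pCO2 computation
#'
#' Empirical linear correction, evaluated at the 1500-m pH(25C, 0 dbar) of
#' each profile: adjustment = -0.034529 pH + 0.26709. One scalar per
#' profile; applied to pH only when deriving pCO2, never to the reported pH.
#'
#' @param ph_25c total-scale pH at 25 deg C, 0 dbar, at the 1500 m level
#' @return pH correction (pH units)
#' @export
eq1_adjustment <- function(ph_25c) {
  -0.034529 * ph_25c + 0.26709
}

#' Deep crossover adjustment of a float pH profile
#'
#' Compares measured float pH(in-situ) with a reference estimate (a
#' function of T, S, P, O2 trained on deep ship data) at the reference
#' level nearest 1500 m (within `window`), and adds the resulting offset to
#' every pH value in the profile. Profiles with no level in the window are
#' flagged unadjustable and dropped.
#'
#' @param floats float level table
#' @param reference function(temp, sal, pres, oxygen) -> pH, e.g. from
#'   [generate_reference_ph_algorithm()]
#' @param window depth window for the reference level, m (default
#'   c(1400, 1600); the nearest in-window level to 1500 m is used)
#' @return list with `floats` (adjusted table, unadjustable profiles
#'   removed) and `crossover` (per-profile reference depth, measured and
#'   estimated pH, offset applied)
#' @export
crossover_adjust <- function(floats, reference, window = c(1400, 1600)) {
  ids <- unique(floats$profile_id)
  if (!length(ids)) {
    return(list(floats = floats,
                crossover = data.frame(profile_id = character(0),
                                       ref_depth = numeric(0),
                                       ph_measured = numeric(0),
                                       ph_expected = numeric(0),
                                       offset = numeric(0),
                                       adjustable = logical(0))))
  }
  rows <- lapply(ids, function(id) {
    p <- floats[floats$profile_id == id, , drop = FALSE]
    inw <- which(p$depth >= window[1] & p$depth <= window[2] &
                   is.finite(p$ph_insitu) & is.finite(p$oxygen))
    if (!length(inw)) {
      return(data.frame(profile_id = id, ref_depth = NA_real_,
                        ph_measured = NA_real_, ph_expected = NA_real_,
                        offset = NA_real_, adjustable = FALSE,
                        stringsAsFactors = FALSE))
    }
    j <- inw[which.min(abs(p$depth[inw] - 1500))]
    expd <- reference(p$temp[j], p$sal[j], p$pressure[j], p$oxygen[j])
    data.frame(profile_id = id, ref_depth = p$depth[j],
               ph_measured = p$ph_insitu[j], ph_expected = expd,
               offset = expd - p$ph_insitu[j], adjustable = TRUE,
               stringsAsFactors = FALSE)
  })
  cross <- do.call(rbind, rows)
  bad <- cross$profile_id[!cross$adjustable]
  if (length(bad)) {
    warning(length(bad), " profile(s) unadjustable: no level in [",
            window[1], ", ", window[2], "] m")
  }
  adj <- floats[!floats$profile_id %in% bad, , drop = FALSE]
  off <- cross$offset[match(adj$profile_id, cross$profile_id)]
  adj$ph_insitu <- adj$ph_insitu + off
  list(floats = adj, crossover = cross)
}

#' Float pCO2 (and derived DIC and pH at 25 C) from adjusted pH
#'
#' Implements the float carbon processing chain: per level, pH(in-situ) is
#' converted to pH(25C, 0 dbar) with estimated TA and Redfield nutrients;
#' the pH-dependent correction [eq1_adjustment()] is evaluated once per
#' profile at the level nearest 1500 m and added to every pH value of the
#' profile (in-situ by default) before the final (pH, TA) -> pCO2 solve.
#' DIC reported alongside comes from the uncorrected (pH, TA) state, as the
#' correction applies to the pCO2 derivation only.
#'
#' @param floats crossover-adjusted float level table
#' @param apply_eq1 logical; set FALSE to skip the pH-dependent correction
#' @param correct_at "insitu" (default) adds the correction to pH in-situ
#'   before the in-situ solve; "ph25" adds it on the 25C scale instead
#' @return `floats` with ph_25c, eq1_corr, pco2 and dic columns added;
#'   profiles lacking a 1400-1600 m level are dropped with a warning
#' @export
float_pco2 <- function(floats, apply_eq1 = TRUE,
                       correct_at = c("insitu", "ph25")) {
  correct_at <- match.arg(correct_at)
  nut <- nutrients_from_nitrate(floats$nitrate,
                                good = is.finite(floats$nitrate))
  floats$ph_25c <- convert_ph_conditions(
    floats$ph_insitu, floats$ta_estimated, floats$temp, floats$sal,
    floats$pressure, silicate = nut$silicate, phosphate = nut$phosphate)
  # uncorrected carbon state (reported DIC)
  st <- carb_solve(ph = floats$ph_insitu, ta = floats$ta_estimated,
                   temp = floats$temp, sal = floats$sal, pres = floats$pressure,
                   silicate = nut$silicate, phosphate = nut$phosphate)
  floats$dic <- st$dic

  ids <- unique(floats$profile_id)
  corr <- vapply(ids, function(id) {
    p <- floats[floats$profile_id == id, , drop = FALSE]
    inw <- which(p$depth >= 1400 & p$depth <= 1600 & is.finite(p$ph_25c))
    if (!length(inw)) return(NA_real_)
    j <- inw[which.min(abs(p$depth[inw] - 1500))]
    eq1_adjustment(p$ph_25c[j])
  }, numeric(1))
  names(corr) <- ids
  bad <- ids[is.na(corr)]
  if (length(bad)) {
    warning(length(bad),
            " profile(s) dropped in pCO2 step: no 1400-1600 m pH(25C) level")
    floats <- floats[!floats$profile_id %in% bad, , drop = FALSE]
  }
  cc <- corr[as.character(floats$profile_id)]
  if (!apply_eq1) cc <- 0 * cc
  floats$eq1_corr <- cc
  nut <- nutrients_from_nitrate(floats$nitrate,
                                good = is.finite(floats$nitrate))
  if (correct_at == "insitu") {
    ph_for_pco2 <- floats$ph_insitu + cc
  } else {
    ph25_corr <- floats$ph_25c + cc
    # re-express the corrected 25C pH at in-situ conditions
    ph_for_pco2 <- vapply(seq_len(nrow(floats)), function(i) {
      convert_ph_conditions(ph25_corr[i], floats$ta_estimated[i], 25,
                            floats$sal[i], 0,
                            silicate = nut$silicate[i],
                            phosphate = nut$phosphate[i],
                            temp_out = floats$temp[i],
                            pres_out = floats$pressure[i])
    }, numeric(1))
  }
  floats$pco2 <- carb_solve(ph = ph_for_pco2, ta = floats$ta_estimated,
                            temp = floats$temp, sal = floats$sal,
                            pres = floats$pressure,
                            silicate = nut$silicate,
                            phosphate = nut$phosphate)$pco2
  floats
}
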