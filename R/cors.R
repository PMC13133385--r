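# CORS (carbon and oxygen relative to saturation) surface analysis.
#
# Surface dissolved O2 and CO2 are compared with their saturation values;
# regressing delta-CO2 on delta-O2 per platform separates shared biological
# / physical forcing (the slope) from a platform-specific CO2 measurement
# offset (the y-intercept). The float-minus-ship intercept difference,
# divided by the CO2 solubility at representative surface conditions,
# converts to a surface pCO2 bias in uatm.

X_O2_AIR <- 0.20946  # dry-air O2 mole fraction

#' O2 saturation at local sea-level pressure
#'
#' Rescales the 1-atm saturation value to in-situ sea-level pressure:
#' O2sat(SLP) = O2sat(1 atm) x (P_SLP - P_Sw) / (P_1atm - P_Sw).
#'
#' @param o2_sat_1atm saturation concentration at 1 atm, umol kg-1
#' @param p_slp sea-level pressure, atm
#' @param p_sw water vapor pressure, atm (must be < p_slp)
#' @return saturation concentration at SLP, umol kg-1
#' @export
o2_saturation_slp <- function(o2_sat_1atm, p_slp, p_sw) {
  if (any(p_sw >= p_slp)) {
    stop("o2_saturation_slp: vapor pressure must be below sea-level pressure")
  }
  o2_sat_1atm * (p_slp - p_sw) / (1 - p_sw)
}

#' CO2 saturation concentration from atmospheric xCO2
#'
#' Equilibrium pCO2 is xCO2_air x (P_SLP - P_Sw) (ppm and atm in, uatm
#' out); the saturation concentration follows from Henry's law with the
#' Weiss (1974) solubility: CO2sat = K0 x pCO2_equilibrium.
#'
#' @param xco2_air dry-air CO2 mole fraction, ppm
#' @param p_slp sea-level pressure, atm
#' @param p_sw water vapor pressure, atm
#' @param temp,sal surface temperature (deg C) and salinity
#' @return list with `pco2_equilibrium` (uatm) and `co2_sat` (umol kg-1)
#' @export
co2_saturation <- function(xco2_air, p_slp, p_sw, temp, sal) {
  if (any(p_sw >= p_slp)) {
    stop("co2_saturation: vapor pressure must be below sea-level pressure")
  }
  pco2_eq <- xco2_air * (p_slp - p_sw)
  list(pco2_equilibrium = pco2_eq,
       co2_sat = k0_weiss(temp, sal) * pco2_eq)
}

#' Surface gas saturation states for CORS
#'
#' Builds delta-O2 and delta-CO2 for a set of surface records. Dissolved
#' CO2 is obtained from each platform's surface pCO2 via Henry's law at the
#' record's temperature and salinity; O2 saturation uses the Garcia &
#' Gordon 1-atm value rescaled to the record's sea-level pressure.
#'
#' @param surface data.frame with temp, sal, oxygen (umol kg-1), pco2
#'   (uatm), and year, month
#' @param xco2_series data.frame (year, month, xco2 ppm)
#' @param slp_series data.frame (year, month, slp atm)
#' @return `surface` with p_sw, p_slp, xco2_air, o2_sat_slp, co2_sat,
#'   delta_o2, delta_co2 columns added
#' @export
surface_gas_state <- function(surface, xco2_series, slp_series) {
  key <- function(d) paste(d$year, d$month)
  xc <- xco2_series$xco2[match(key(surface), key(xco2_series))]
  sl <- slp_series$slp[match(key(surface), key(slp_series))]
  if (any(is.na(xc)) || any(is.na(sl))) {
    stop("surface_gas_state: missing xCO2 or SLP for some (year, month)")
  }
  psw <- vapor_pressure(surface$temp, surface$sal)
  o2s1 <- o2_saturation_1atm(surface$temp, surface$sal)
  surface$p_sw <- psw
  surface$p_slp <- sl
  surface$xco2_air <- xc
  surface$o2_sat_slp <- o2_saturation_slp(o2s1, sl, psw)
  cs <- co2_saturation(xc, sl, psw, surface$temp, surface$sal)
  surface$pco2_equilibrium <- cs$pco2_equilibrium
  surface$co2_sat <- cs$co2_sat
  surface$co2_obs <- k0_weiss(surface$temp, surface$sal) * surface$pco2
  surface$delta_o2 <- surface$oxygen - surface$o2_sat_slp
  surface$delta_co2 <- surface$co2_obs - surface$co2_sat
  surface
}

#' CORS regression fit per platform
#'
#' Ordinary least squares of delta-CO2 on delta-O2 for each platform, with
#' Pearson r and its two-sided p-value, and the float-minus-ship intercept
#' offset.
#'
#' @param states surface gas state table with a `platform` column
#'   ("float" / "ship") and delta_o2, delta_co2 columns
#' @return list with `fits` (per-platform slope, intercept, r, p, n) and
#'   `intercept_offset` (float minus ship, umol kg-1)
#' @export
cors_fit <- function(states) {
  fit1 <- function(sub) {
    if (nrow(sub) < 3) stop("cors_fit: need at least 3 points per platform")
    if (stats::var(sub$delta_o2) == 0) {
      stop("cors_fit: degenerate delta-O2 variance")
    }
    m <- stats::lm(delta_co2 ~ delta_o2, data = sub)
    ct <- stats::cor.test(sub$delta_o2, sub$delta_co2)
    data.frame(slope = unname(stats::coef(m)[2]),
               intercept = unname(stats::coef(m)[1]),
               r = unname(ct$estimate), p = ct$p.value, n = nrow(sub))
  }
  fits <- do.call(rbind, lapply(split(states, states$platform), fit1))
  fits$platform <- rownames(fits)
  off <- if (all(c("float", "ship") %in% fits$platform)) {
    fits$intercept[fits$platform == "float"] -
      fits$intercept[fits$platform == "ship"]
  } else NA_real_
  list(fits = fits, intercept_offset = off)
}

#' Convert a dissolved-CO2 intercept offset to a surface pCO2 bias
#'
#' Divides the CORS intercept offset (umol kg-1) by the Weiss CO2
#' solubility at representative surface conditions (default 1 deg C, S =
#' 35), giving the implied pCO2 difference in uatm.
#'
#' @param offset intercept offset, umol kg-1 (float minus ship)
#' @param temp,sal representative surface conditions
#' @return implied surface pCO2 bias, uatm
#' @examples
#' offset_to_pco2_bias(0.84)  # ~14 uatm
#' @export
offset_to_pco2_bias <- function(offset, temp = 1, sal = 35) {
  offset / k0_weiss(temp, sal)
}
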