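# Anthropogenic carbon back-calculation (delta-C* and TrOCA) and the
# three-fold unacidified-water screen for Circumpolar Deep Water.
#
# Only ship-side data enter the screen: float-derived carbon values are
# exactly what is under scrutiny, so they are never used to decide which
# water is anthropogenically unperturbed.

#' Preformed total alkalinity
#'
#' Multiple linear regression estimate of preformed TA for Antarctic
#' surface waters: TA0 = 378.1 + 55.22 S + 0.0716 PO - 1.236 theta, with
#' PO = O2 + 170 PO4 the quasi-conservative phosphate-oxygen tracer.
#'
#' @param sal practical salinity
#' @param po PO tracer, umol kg-1 (use [po_tracer()])
#' @param theta potential temperature, deg C
#' @return preformed TA, umol kg-1
#' @export
preformed_ta <- function(sal, po, theta) {
  378.1 + 55.22 * sal + 0.0716 * po - 1.236 * theta
}

#' Quasi-conservative PO tracer
#'
#' @param oxygen O2, umol kg-1
#' @param phosphate PO4, umol kg-1
#' @return PO = O2 + 170 PO4, umol kg-1
#' @export
po_tracer <- function(oxygen, phosphate) oxygen + 170 * phosphate

#' Biological DIC change since subduction
#'
#' Remineralization / calcium-carbonate dissolution contribution to DIC:
#' -117/170 (O2 - O2sat) + 1/2 (TA - TA0 - 16/170 (O2 - O2sat)) - 106/104 N*anom.
#'
#' @param oxygen,o2_sat O2 and its saturation value, umol kg-1
#' @param ta,ta0 measured and preformed TA, umol kg-1
#' @param nstar_anom N* anomaly from the mean, umol kg-1
#' @return delta-C_bio, umol kg-1
#' @export
delta_c_bio <- function(oxygen, o2_sat, ta, ta0, nstar_anom = 0) {
  aou <- oxygen - o2_sat
  -117 / 170 * aou + 0.5 * (ta - ta0 - 16 / 170 * aou) - 106 / 104 * nstar_anom
}

#' N* nitrogen-cycle tracer
#'
#' N* = 0.87 (NO3 - 16 PO4 + 2.90); anomalies are taken relative to the
#' mean over the reference population (all screened-candidate ship levels).
#'
#' @param nitrate,phosphate umol kg-1
#' @return N*, umol kg-1
#' @export
nstar <- function(nitrate, phosphate) 0.87 * (nitrate - 16 * phosphate + 2.90)

#' Anthropogenic carbon by the delta-C* back-calculation
#'
#' C_anth = C_m - C_280 - delta-C_bio - delta-C_dis, where C_280 is the DIC
#' of water with preformed alkalinity TA0 equilibrated with a 280 uatm
#' atmosphere, solved by the carbonate module at (theta, 0 dbar) --
#' preformed conditions -- and delta-C_dis is a configured air-sea
#' disequilibrium scalar (default 0).
#'
#' @param dic measured DIC, umol kg-1
#' @param ta measured TA, umol kg-1
#' @param oxygen O2, umol kg-1
#' @param nitrate,phosphate,silicate nutrients, umol kg-1
#' @param sal practical salinity
#' @param theta potential temperature, deg C
#' @param nstar_anom N* anomaly from the reference mean, umol kg-1
#' @param delta_c_dis air-sea disequilibrium DIC, umol kg-1
#' @return data.frame of all intermediate tracers (c_280, ta0, po,
#'   delta_c_bio, delta_c_star) and `canth`
#' @export
canth_delta_c_star <- function(dic, ta, oxygen, nitrate, phosphate, silicate,
                               sal, theta, nstar_anom = 0, delta_c_dis = 0) {
  po <- po_tracer(oxygen, phosphate)
  ta0 <- preformed_ta(sal, po, theta)
  o2s <- o2_saturation_1atm(theta, sal)
  dcb <- delta_c_bio(oxygen, o2s, ta, ta0, nstar_anom)
  c280 <- carb_solve(ta = ta0, pco2 = 280, temp = theta, sal = sal, pres = 0,
                     silicate = silicate, phosphate = phosphate)$dic
  dcs <- dic - c280 - dcb
  data.frame(c_m = dic, c_280 = c280, ta0 = ta0, po = po, o2_sat = o2s,
             delta_c_bio = dcb, nstar_anom = nstar_anom,
             delta_c_star = dcs, delta_c_dis = delta_c_dis,
             canth = dcs - delta_c_dis)
}

#' Anthropogenic carbon by the TrOCA method
#'
#' TrOCA = O2 + 1.279 (DIC - TA/2); the preindustrial reference is
#' TrOCA0 = exp(7.511 - 1.087e-2 theta - 7.81e5 / TA^2) and
#' C_anth = (TrOCA - TrOCA0) / 1.279.
#'
#' @param oxygen O2, umol kg-1
#' @param dic DIC, umol kg-1
#' @param ta TA, umol kg-1 (must be > 0)
#' @param theta potential temperature, deg C
#' @return data.frame with troca, troca0 and `canth`
#' @export
canth_troca <- function(oxygen, dic, ta, theta) {
  if (any(ta <= 0)) stop("canth_troca: TA must be positive")
  troca <- oxygen + 1.279 * (dic - 0.5 * ta)
  troca0 <- exp(7.511 - 1.087e-2 * theta - 7.81e5 / ta^2)
  data.frame(troca = troca, troca0 = troca0,
             canth = (troca - troca0) / 1.279)
}

#' Classify Circumpolar Deep Water
#'
#' UCDW: 2.5 < theta < 3 deg C and 27.4 < sigma0 < 27.7;
#' LCDW: 0 < theta < 2.5 deg C and sigma0 > 27.7 (strict inequalities).
#'
#' @param theta potential temperature, deg C
#' @param sigma0 potential density anomaly, kg m-3 - 1000
#' @return character vector in {"UCDW", "LCDW", "none"}
#' @export
classify_watermass <- function(theta, sigma0) {
  ifelse(theta > 2.5 & theta < 3 & sigma0 > 27.4 & sigma0 < 27.7, "UCDW",
         ifelse(theta > 0 & theta < 2.5 & sigma0 > 27.7, "LCDW", "none"))
}

#' Screen matched pairs for unacidified subsurface water
#'
#' Applies the three-fold constraint on the ship side of each matched
#' float-ship level pair: (1) depth > 200 m, (2) potential temperature and
#' potential density characteristic of UCDW or LCDW, (3) ship-based
#' delta-C* anthropogenic carbon < `canth_max` umol kg-1. Pairs with
#' missing ship carbon data are excluded with a warning.
#'
#' @param pairs matched pair table from [match_float_ship()] (ship-side
#'   temp/sal/pressure/DIC/TA/nutrient columns present)
#' @param canth_max anthropogenic carbon threshold, umol kg-1 (default 10)
#' @param delta_c_dis air-sea disequilibrium scalar passed to the delta-C*
#'   calculation, umol kg-1
#' @return `pairs` with watermass, canth (delta-C*) and canth_troca columns
#'   attached, restricted to rows passing the screen
#' @export
screen_unacidified <- function(pairs, canth_max = 10, delta_c_dis = 0) {
  need <- is.finite(pairs$ship_dic) & is.finite(pairs$ship_ta) &
    is.finite(pairs$oxygen_s)
  if (any(!need)) {
    warning(sum(!need), " pair(s) excluded: missing ship carbon data")
    pairs <- pairs[need, , drop = FALSE]
  }
  ts <- theta_sigma0(pairs$sal_s, pairs$temp_s, pairs$ship_pres)
  pairs$theta_s <- ts$theta
  pairs$sigma0_s <- ts$sigma0
  pairs$watermass <- classify_watermass(ts$theta, ts$sigma0)
  cand <- pairs$ship_depth > 200 & pairs$watermass != "none"
  # N* anomaly referenced to the screened-candidate population mean
  ns <- nstar(pairs$nitrate_s, pairs$ship_pho)
  ns_anom <- ns - mean(ns[cand], na.rm = TRUE)
  dcs <- canth_delta_c_star(pairs$ship_dic, pairs$ship_ta, pairs$oxygen_s,
                            pairs$nitrate_s, pairs$ship_pho, pairs$ship_sil,
                            pairs$sal_s, ts$theta,
                            nstar_anom = ns_anom, delta_c_dis = delta_c_dis)
  pairs$canth <- dcs$canth
  pairs$canth_troca <- canth_troca(pairs$oxygen_s, pairs$ship_dic,
                                   pairs$ship_ta, ts$theta)$canth
  keep <- cand & pairs$canth < canth_max
  pairs[keep, , drop = FALSE]
}
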