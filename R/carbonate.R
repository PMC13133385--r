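# Marine carbonate system solver, total pH scale.
#
# Constant set fixed to the choices used for float pCO2 processing:
# K1/K2 Lueker et al. (2000), KSO4 Dickson (1990a), KF Perez & Fraga (1987),
# total borate Lee et al. (2010); the remaining constants (KB Dickson 1990b,
# KW and the phosphate/silicate constants Millero 1995, pressure corrections
# from the Millero 1995 compilation, Weiss 1974 K0 and fugacity virial
# coefficients) follow the CO2SYS-family conventions bundled with the Lueker
# option. All equilibrium solves are done in mol kg-1 on the total hydrogen
# ion scale; user-facing concentrations are umol kg-1 and pressures uatm.

R_GAS_BAR <- 83.1451 # ml bar K-1 mol-1

#' CO2 solubility in seawater (Weiss 1974)
#'
#' Henry's-law solubility coefficient K0 of CO2 in seawater, from the
#' two-term temperature fit plus salinity polynomial of Weiss (1974).
#'
#' @param temp temperature, deg C (valid roughly -2 to 35)
#' @param sal practical salinity (0 to 40)
#' @return K0 in mol kg-1 atm-1
#' @examples
#' k0_weiss(1, 35)       # ~0.0606 mol kg-1 atm-1
#' @export
k0_weiss <- function(temp, sal) {
  if (any(temp < -3 | temp > 40 | sal < 0 | sal > 45)) {
    stop("k0_weiss: temperature or salinity outside fitted range")
  }
  tk100 <- (temp + 273.15) / 100
  lnK0 <- -60.2409 + 93.4517 / tk100 + 23.3585 * log(tk100) +
    sal * (0.023517 - 0.023656 * tk100 + 0.0047036 * tk100^2)
  exp(lnK0)
}

#' Redfield nutrient estimates from nitrate
#'
#' Silicate and phosphate are not measured by the floats; when nitrate is of
#' good quality they are estimated as silicate = nitrate x 2.5 and
#' phosphate = nitrate / 16, otherwise both are set to 0.
#'
#' @param nitrate nitrate, umol kg-1
#' @param good logical, nitrate quality flag is good
#' @return list with `silicate` and `phosphate` (umol kg-1)
#' @export
nutrients_from_nitrate <- function(nitrate, good = TRUE) {
  good <- good & is.finite(nitrate)
  sil <- ifelse(good, nitrate * 2.5, 0)
  pho <- ifelse(good, nitrate / 16, 0)
  list(silicate = sil, phosphate = pho)
}

# Equilibrium constants at (T, S, P), all returned on the total scale at
# in-situ pressure (KS, KF on the free scale as used inside the alkalinity
# equation). Vectorised over all arguments.
carb_constants <- function(temp, sal, pres = 0) {
  n <- max(length(temp), length(sal), length(pres))
  temp <- rep_len(temp, n); sal <- rep_len(sal, n); pres <- rep_len(pres, n)
  TK <- temp + 273.15
  lnTK <- log(TK)
  sqS <- sqrt(sal)
  Pbar <- pres / 10
  RT <- R_GAS_BAR * TK
  IonS <- 19.924 * sal / (1000 - 1.005 * sal)

  TB <- 0.0004326 * sal / 35                 # Lee et al. (2010)
  TS <- (0.14 / 96.062) * sal / 1.80655      # Morris & Riley
  TF <- (0.000067 / 18.998) * sal / 1.80655  # Riley

  # bisulfate, Dickson (1990a), free scale, mol kg-SW
  lnKS <- -4276.1 / TK + 141.328 - 23.093 * lnTK +
    (-13856 / TK + 324.57 - 47.986 * lnTK) * sqrt(IonS) +
    (35474 / TK - 771.54 + 114.723 * lnTK) * IonS -
    2698 / TK * IonS^1.5 + 1776 / TK * IonS^2
  KS <- exp(lnKS) * (1 - 0.001005 * sal)

  # hydrogen fluoride, Perez & Fraga (1987)
  KF <- exp(874 / TK - 9.68 + 0.111 * sqS)

  SWStoTOT <- (1 + TS / KS) / (1 + TS / KS + TF / KF)

  # carbonic acid, Lueker et al. (2000), total scale -> SWS for P-correction
  pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * lnTK - 0.011555 * sal + 0.0001152 * sal^2
  pK2 <- 471.78 / TK + 25.929 - 3.16967 * lnTK - 0.01781 * sal + 0.0001122 * sal^2
  K1 <- 10^(-pK1) / SWStoTOT
  K2 <- 10^(-pK2) / SWStoTOT

  # boric acid, Dickson (1990b), total scale -> SWS
  lnKB <- (-8966.9 - 2890.53 * sqS - 77.942 * sal + 1.728 * sqS * sal -
             0.0996 * sal^2) / TK +
    148.0248 + 137.1942 * sqS + 1.62142 * sal +
    (-24.4344 - 25.085 * sqS - 0.2474 * sal) * lnTK + 0.053105 * sqS * TK
  KB <- exp(lnKB) / SWStoTOT

  # water, Millero (1995), SWS
  lnKW <- 148.9802 - 13847.26 / TK - 23.6521 * lnTK +
    (-5.977 + 118.67 / TK + 1.0495 * lnTK) * sqS - 0.01615 * sal
  KW <- exp(lnKW)

  # phosphoric acid and silicic acid, Millero (1995), SWS
  KP1 <- exp(-4576.752 / TK + 115.525 - 18.453 * lnTK +
               (-106.736 / TK + 0.69171) * sqS + (-0.65643 / TK - 0.01844) * sal)
  KP2 <- exp(-8814.715 / TK + 172.0883 - 27.927 * lnTK +
               (-160.34 / TK + 1.3566) * sqS + (0.37335 / TK - 0.05778) * sal)
  KP3 <- exp(-3070.75 / TK - 18.141 +
               (17.27039 / TK + 2.81197) * sqS + (-44.99486 / TK - 0.09984) * sal)
  KSi <- exp(-8904.2 / TK + 117.385 - 19.334 * lnTK +
               (-458.79 / TK + 3.5913) * sqrt(IonS) +
               (188.74 / TK - 1.5998) * IonS +
               (-12.1652 / TK + 0.07871) * IonS^2) * (1 - 0.001005 * sal)

  # pressure corrections (Millero 1995 compilation as used by CO2SYS),
  # applied on the SWS scale (free scale for KS, KF)
  pfac <- function(dV, Ka) exp((-dV + 0.5 * Ka * Pbar) * Pbar / RT)
  K1  <- K1  * pfac(-25.5  + 0.1271 * temp,                    (-3.08 + 0.0877 * temp) / 1000)
  K2  <- K2  * pfac(-15.82 - 0.0219 * temp,                    (1.13 - 0.1475 * temp) / 1000)
  KB  <- KB  * pfac(-29.48 + 0.1622 * temp + 0.002608 * temp^2, -2.84 / 1000)
  KW  <- KW  * pfac(-20.02 + 0.1119 * temp - 0.001409 * temp^2, (-5.13 + 0.0794 * temp) / 1000)
  KF  <- KF  * pfac(-9.78  - 0.009  * temp - 0.000942 * temp^2, (-3.91 + 0.054 * temp) / 1000)
  KS  <- KS  * pfac(-18.03 + 0.0466 * temp + 0.000316 * temp^2, (-4.53 + 0.09 * temp) / 1000)
  KP1 <- KP1 * pfac(-14.51 + 0.1211 * temp - 0.000321 * temp^2, (-2.67 + 0.0427 * temp) / 1000)
  KP2 <- KP2 * pfac(-23.12 + 0.1758 * temp - 0.002647 * temp^2, (-5.15 + 0.09 * temp) / 1000)
  KP3 <- KP3 * pfac(-26.57 + 0.202  * temp - 0.003042 * temp^2, (-4.08 + 0.0714 * temp) / 1000)
  KSi <- KSi * pfac(-29.48 + 0.1622 * temp + 0.002608 * temp^2, -2.84 / 1000)

  # back to the total scale with pressure-corrected KS, KF
  SWStoTOT <- (1 + TS / KS) / (1 + TS / KS + TF / KF)
  FREEtoTOT <- 1 + TS / KS
  K1 <- K1 * SWStoTOT; K2 <- K2 * SWStoTOT; KB <- KB * SWStoTOT
  KW <- KW * SWStoTOT; KP1 <- KP1 * SWStoTOT; KP2 <- KP2 * SWStoTOT
  KP3 <- KP3 * SWStoTOT; KSi <- KSi * SWStoTOT

  # Weiss (1974) solubility and fugacity-coefficient factor (pCO2 = fCO2/FugFac)
  K0 <- k0_weiss(temp, sal)
  Delta <- 57.7 - 0.118 * TK
  bvir <- -1636.75 + 12.0408 * TK - 0.0327957 * TK^2 + 3.16528e-5 * TK^3
  FugFac <- exp((bvir + 2 * Delta) * 1.01325 / RT)

  list(K0 = K0, K1 = K1, K2 = K2, KB = KB, KW = KW, KS = KS, KF = KF,
       KP1 = KP1, KP2 = KP2, KP3 = KP3, KSi = KSi,
       TB = TB, TS = TS, TF = TF,
       FREEtoTOT = FREEtoTOT, FugFac = FugFac, n = n)
}

# Total alkalinity (mol kg-1) from H+ (total scale) and the non-carbonate
# totals; carbonate contribution passed in as carb_alk.
.alk_noncarb <- function(H, k, TP, TSi) {
  BAlk <- k$TB * k$KB / (k$KB + H)
  OH <- k$KW / H
  Hfree <- H / k$FREEtoTOT
  HSO4 <- k$TS / (1 + k$KS / Hfree)
  HF <- k$TF / (1 + k$KF / Hfree)
  PhosTop <- k$KP1 * k$KP2 * H + 2 * k$KP1 * k$KP2 * k$KP3 - H^3
  PhosBot <- H^3 + k$KP1 * H^2 + k$KP1 * k$KP2 * H + k$KP1 * k$KP2 * k$KP3
  PAlk <- TP * PhosTop / PhosBot
  SiAlk <- TSi * k$KSi / (k$KSi + H)
  BAlk + OH + PAlk + SiAlk - Hfree - HSO4 - HF
}

# TA (mol kg-1) at given pH for fixed DIC (mol kg-1)
.alk_from_ph_dic <- function(ph, dic, k, TP, TSi) {
  H <- 10^(-ph)
  Denom <- H^2 + k$K1 * H + k$K1 * k$K2
  CAlk <- dic * k$K1 * (H + 2 * k$K2) / Denom
  CAlk + .alk_noncarb(H, k, TP, TSi)
}

# TA (mol kg-1) at given pH for fixed CO2* (mol kg-1)
.alk_from_ph_co2 <- function(ph, co2, k, TP, TSi) {
  H <- 10^(-ph)
  CAlk <- co2 * k$K1 / H + 2 * co2 * k$K1 * k$K2 / H^2
  CAlk + .alk_noncarb(H, k, TP, TSi)
}

# Vectorised safeguarded Newton / bisection on pH in [3, 12].
# resid(ph) must be monotonically increasing in pH; target residual 0.
.solve_ph <- function(resid, n, tol = 1e-10, maxit = 200) {
  ph <- rep(8, n); lo <- rep(3, n); hi <- rep(12, n)
  for (it in seq_len(maxit)) {
    r <- resid(ph)
    done <- abs(r) < tol
    if (all(done)) return(ph)
    hi <- ifelse(r > 0, pmin(hi, ph), hi)
    lo <- ifelse(r < 0, pmax(lo, ph), lo)
    dr <- (resid(ph + 1e-6) - r) / 1e-6
    step <- ifelse(dr > 0, r / dr, NA_real_)
    cand <- ph - step
    bad <- !is.finite(cand) | cand <= lo | cand >= hi
    cand[bad] <- (lo[bad] + hi[bad]) / 2
    ph <- ifelse(done, ph, cand)
  }
  r <- resid(ph)
  if (any(abs(r) >= tol)) {
    stop(sprintf(
      "carbonate solver failed to converge for %d state(s); worst |dTA| = %.3g umol kg-1",
      sum(abs(r) >= tol), max(abs(r)) * 1e6))
  }
  ph
}

#' Solve the marine carbonate system
#'
#' Solves the full carbonate system from any two of pH (total scale), DIC,
#' TA and pCO2, at the stated temperature, salinity and pressure, including
#' borate, water, phosphate and silicate contributions to alkalinity.
#' Supported input pairs: (ph, ta), (dic, ta), (ta, pco2), (ph, dic).
#'
#' @param ph pH on the total scale at the input conditions
#' @param dic dissolved inorganic carbon, umol kg-1
#' @param ta total alkalinity, umol kg-1
#' @param pco2 CO2 partial pressure, uatm
#' @param temp in-situ temperature, deg C
#' @param sal practical salinity
#' @param pres pressure, dbar (0 for surface / 25C reference conditions)
#' @param silicate,phosphate nutrient concentrations, umol kg-1
#' @return data.frame with columns ph, dic, ta, pco2 (and the input
#'   conditions); one row per state. pCO2 is a partial pressure, obtained
#'   from fugacity with the Weiss (1974) virial correction.
#' @examples
#' carb_solve(ta = 2350, pco2 = 280, temp = 2, sal = 34.7, pres = 0)
#' @export
carb_solve <- function(ph = NULL, dic = NULL, ta = NULL, pco2 = NULL,
                       temp, sal, pres = 0, silicate = 0, phosphate = 0) {
  given <- c(ph = !is.null(ph), dic = !is.null(dic),
             ta = !is.null(ta), pco2 = !is.null(pco2))
  pair <- paste(names(given)[given], collapse = "+")
  if (sum(given) != 2) {
    stop("carb_solve: exactly two of ph, dic, ta, pco2 must be given")
  }
  if (any(vapply(list(ph, dic, ta, pco2),
                 function(x) !is.null(x) && length(x) == 0, logical(1)))) {
    return(data.frame(ph = numeric(0), dic = numeric(0), ta = numeric(0),
                      pco2 = numeric(0), temp = numeric(0), sal = numeric(0),
                      pres = numeric(0), silicate = numeric(0),
                      phosphate = numeric(0)))
  }
  k <- carb_constants(temp, sal, pres)
  n <- max(k$n, length(ph), length(dic), length(ta), length(pco2),
           length(silicate), length(phosphate))
  TP <- rep_len(phosphate, n) * 1e-6
  TSi <- rep_len(silicate, n) * 1e-6
  if (!is.null(ph)) ph <- rep_len(ph, n)
  if (!is.null(dic)) dic <- rep_len(dic, n) * 1e-6
  if (!is.null(ta)) ta <- rep_len(ta, n) * 1e-6
  if (!is.null(pco2)) pco2 <- rep_len(pco2, n)

  if (pair == "ph+ta") {
    H <- 10^(-ph)
    CAlk <- ta - .alk_noncarb(H, k, TP, TSi)
    dic <- CAlk * (H^2 + k$K1 * H + k$K1 * k$K2) / (k$K1 * (H + 2 * k$K2))
  } else if (pair == "ph+dic") {
    ta <- .alk_from_ph_dic(ph, dic, k, TP, TSi)
  } else if (pair == "dic+ta") {
    ph <- .solve_ph(function(p) .alk_from_ph_dic(p, dic, k, TP, TSi) - ta, n)
  } else if (pair == "ta+pco2") {
    co2 <- k$K0 * pco2 * 1e-6 * k$FugFac
    ph <- .solve_ph(function(p) .alk_from_ph_co2(p, co2, k, TP, TSi) - ta, n)
    H <- 10^(-ph)
    dic <- co2 * (1 + k$K1 / H + k$K1 * k$K2 / H^2)
  } else {
    stop("carb_solve: unsupported input pair ", pair)
  }
  H <- 10^(-ph)
  co2 <- dic * H^2 / (H^2 + k$K1 * H + k$K1 * k$K2)
  fco2 <- co2 / k$K0
  pco2 <- fco2 / k$FugFac * 1e6
  data.frame(ph = ph, dic = dic * 1e6, ta = ta * 1e6, pco2 = pco2,
             temp = rep_len(temp, n), sal = rep_len(sal, n),
             pres = rep_len(pres, n),
             silicate = TSi * 1e6, phosphate = TP * 1e6)
}

#' Convert pH between temperature/pressure conditions
#'
#' Re-expresses a total-scale pH measured at in-situ conditions at another
#' temperature and pressure (default 25 deg C, 0 dbar), conserving DIC and
#' TA across the condition change: the in-situ state is first solved from
#' (pH, TA), then pH is re-solved from the conserved (DIC, TA) at the
#' output conditions.
#'
#' @param ph_insitu total-scale pH at (`temp`, `pres`)
#' @param ta total alkalinity, umol kg-1
#' @param temp,sal,pres in-situ conditions (deg C, practical salinity, dbar)
#' @param silicate,phosphate nutrients, umol kg-1
#' @param temp_out,pres_out output conditions, default 25 deg C and 0 dbar
#' @return total-scale pH at the output conditions
#' @export
convert_ph_conditions <- function(ph_insitu, ta, temp, sal, pres,
                                  silicate = 0, phosphate = 0,
                                  temp_out = 25, pres_out = 0) {
  st <- carb_solve(ph = ph_insitu, ta = ta, temp = temp, sal = sal,
                   pres = pres, silicate = silicate, phosphate = phosphate)
  out <- carb_solve(dic = st$dic, ta = st$ta, temp = temp_out, sal = sal,
                    pres = pres_out, silicate = silicate, phosphate = phosphate)
  out$ph
}
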