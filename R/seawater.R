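# Seawater physical properties: EOS-80 potential temperature and potential
# density anomaly, Garcia & Gordon oxygen solubility, Weiss & Price water
# vapor pressure. All vectorised.

# Adiabatic temperature gradient (deg C / dbar), Bryden (1973) polynomial as
# given by Fofonoff & Millard (1983).
.adtg <- function(sal, temp, pres) {
  ds <- sal - 35
  3.5803e-5 + 8.5258e-6 * temp - 6.836e-8 * temp^2 + 6.6228e-10 * temp^3 +
    (1.8932e-6 - 4.2393e-8 * temp) * ds +
    (1.8741e-8 - 6.7795e-10 * temp + 8.733e-12 * temp^2 -
       5.4481e-14 * temp^3) * pres +
    (-1.1351e-10 + 2.7759e-12 * temp) * ds * pres +
    (-4.6206e-13 + 1.8676e-14 * temp - 2.1687e-16 * temp^2) * pres^2
}

#' Potential temperature (EOS-80)
#'
#' Temperature a parcel at (`sal`, `temp`, `pres`) would have if moved
#' adiabatically to reference pressure `pres_ref`, via the Fofonoff &
#' Millard (1983) 4th-order Runge-Kutta integration of the adiabatic lapse
#' rate. With `pres = 0` and a target pressure as reference this also
#' converts potential to in-situ temperature.
#'
#' @param sal practical salinity
#' @param temp in-situ temperature, deg C
#' @param pres pressure, dbar
#' @param pres_ref reference pressure, dbar (default 0)
#' @return potential temperature, deg C
#' @export
potential_temperature <- function(sal, temp, pres, pres_ref = 0) {
  dp <- pres_ref - pres
  dth <- dp * .adtg(sal, temp, pres)
  th <- temp + 0.5 * dth
  q <- dth
  dth <- dp * .adtg(sal, th, pres + 0.5 * dp)
  th <- th + 0.29289322 * (dth - q)
  q <- 0.58578644 * dth + 0.121320344 * q
  dth <- dp * .adtg(sal, th, pres + 0.5 * dp)
  th <- th + 1.707106781 * (dth - q)
  q <- 3.414213562 * dth - 4.121320344 * q
  dth <- dp * .adtg(sal, th, pres + dp)
  th + (dth - 2 * q) / 6
}

# One-atmosphere equation of state (Millero & Poisson 1981): density kg m-3
.rho_surface <- function(sal, temp) {
  t <- temp
  rw <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  A <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  B <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  C <- 4.8314e-4
  rw + A * sal + B * sal^1.5 + C * sal^2
}

#' Potential density anomaly referenced to the surface
#'
#' sigma0 = rho(S, theta, 0 dbar) - 1000 kg m-3, with theta the potential
#' temperature referenced to 0 dbar and the one-atmosphere EOS-80 density.
#'
#' @inheritParams potential_temperature
#' @return list with `theta` (deg C) and `sigma0` (kg m-3 - 1000)
#' @export
theta_sigma0 <- function(sal, temp, pres) {
  if (any(sal < 0 | sal > 45 | temp < -3 | temp > 45 | pres < 0, na.rm = TRUE)) {
    stop("theta_sigma0: state outside valid seawater range")
  }
  th <- potential_temperature(sal, temp, pres, 0)
  list(theta = th, sigma0 = .rho_surface(sal, th) - 1000)
}

#' Oxygen saturation concentration at 1 atm (Garcia & Gordon 1992)
#'
#' Equilibrium O2 concentration for water-saturated air at 1 atm total
#' pressure, from the Garcia & Gordon (1992) combined fit to the Benson &
#' Krause data, in umol kg-1.
#'
#' @param temp temperature, deg C (-1.8 to 40)
#' @param sal practical salinity (0 to 42)
#' @return O2 saturation concentration, umol kg-1
#' @export
o2_saturation_1atm <- function(temp, sal) {
  if (any(temp < -2 | temp > 40 | sal < 0 | sal > 42)) {
    stop("o2_saturation_1atm: input outside fit range")
  }
  Ts <- log((298.15 - temp) / (273.15 + temp))
  lnC <- 5.80871 + 3.20291 * Ts + 4.17887 * Ts^2 + 5.10006 * Ts^3 -
    9.86643e-2 * Ts^4 + 3.80369 * Ts^5 +
    sal * (-7.01577e-3 - 7.70028e-3 * Ts - 1.13864e-2 * Ts^2 -
             9.51519e-3 * Ts^3) -
    2.75915e-7 * sal^2
  exp(lnC)
}

#' Seawater vapor pressure (Weiss & Price 1980)
#'
#' Water vapor pressure over seawater as a function of surface temperature
#' and salinity, in atm.
#'
#' @param temp temperature, deg C (-2 to 35)
#' @param sal practical salinity (0 to 40)
#' @return vapor pressure, atm
#' @export
vapor_pressure <- function(temp, sal) {
  if (any(temp < -3 | temp > 40 | sal < 0 | sal > 42)) {
    stop("vapor_pressure: input outside fit range")
  }
  TK <- temp + 273.15
  exp(24.4543 - 67.4509 * (100 / TK) - 4.8489 * log(TK / 100) - 0.000544 * sal)
}
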