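#!/usr/bin/env python
"""Independent carbonate-system reference for cross-checking the R solver.

Total pH scale; K1/K2 Lueker et al. (2000), KSO4 Dickson (1990a),
KF Perez & Fraga (1987), total borate Lee et al. (2010), KB Dickson (1990b),
KW/KP/KSi Millero (1995), Millero (1995) pressure corrections, Weiss (1974)
K0 and fugacity virial coefficients -- the CO2SYS-family convention set.

Solved with scipy.optimize.brentq on pH (deliberately a different numerical
strategy from the package's vectorised Newton iteration). Used once to
freeze a Latin-hypercube fixture of reference states; the frozen CSV, not
this script, is what the test suite reads.

Usage: python co2sys_oracle.py out.csv
"""
import sys
import math
import numpy as np
from scipy.optimize import brentq

RGAS = 83.1451


def constants(T, S, P):
    TK = T + 273.15
    lnTK = math.log(TK)
    sq = math.sqrt(S)
    Pbar = P / 10.0
    RT = RGAS * TK
    I = 19.924 * S / (1000.0 - 1.005 * S)

    TB = 0.0004326 * S / 35.0
    TS = (0.14 / 96.062) * S / 1.80655
    TF = (0.000067 / 18.998) * S / 1.80655

    lnKS = (-4276.1 / TK + 141.328 - 23.093 * lnTK
            + (-13856.0 / TK + 324.57 - 47.986 * lnTK) * math.sqrt(I)
            + (35474.0 / TK - 771.54 + 114.723 * lnTK) * I
            - 2698.0 / TK * I ** 1.5 + 1776.0 / TK * I ** 2)
    KS = math.exp(lnKS) * (1 - 0.001005 * S)
    KF = math.exp(874.0 / TK - 9.68 + 0.111 * sq)

    sws2tot = (1 + TS / KS) / (1 + TS / KS + TF / KF)

    pK1 = 3633.86 / TK - 61.2172 + 9.6777 * lnTK - 0.011555 * S + 0.0001152 * S * S
    pK2 = 471.78 / TK + 25.929 - 3.16967 * lnTK - 0.01781 * S + 0.0001122 * S * S
    K1 = 10.0 ** (-pK1) / sws2tot
    K2 = 10.0 ** (-pK2) / sws2tot

    lnKB = ((-8966.9 - 2890.53 * sq - 77.942 * S + 1.728 * sq * S - 0.0996 * S * S) / TK
            + 148.0248 + 137.1942 * sq + 1.62142 * S
            + (-24.4344 - 25.085 * sq - 0.2474 * S) * lnTK + 0.053105 * sq * TK)
    KB = math.exp(lnKB) / sws2tot

    lnKW = (148.9802 - 13847.26 / TK - 23.6521 * lnTK
            + (-5.977 + 118.67 / TK + 1.0495 * lnTK) * sq - 0.01615 * S)
    KW = math.exp(lnKW)

    KP1 = math.exp(-4576.752 / TK + 115.525 - 18.453 * lnTK
                   + (-106.736 / TK + 0.69171) * sq + (-0.65643 / TK - 0.01844) * S)
    KP2 = math.exp(-8814.715 / TK + 172.0883 - 27.927 * lnTK
                   + (-160.34 / TK + 1.3566) * sq + (0.37335 / TK - 0.05778) * S)
    KP3 = math.exp(-3070.75 / TK - 18.141
                   + (17.27039 / TK + 2.81197) * sq + (-44.99486 / TK - 0.09984) * S)
    KSi = math.exp(-8904.2 / TK + 117.385 - 19.334 * lnTK
                   + (-458.79 / TK + 3.5913) * math.sqrt(I)
                   + (188.74 / TK - 1.5998) * I
                   + (-12.1652 / TK + 0.07871) * I * I) * (1 - 0.001005 * S)

    def pf(dV, Ka):
        return math.exp((-dV + 0.5 * Ka * Pbar) * Pbar / RT)

    K1 *= pf(-25.5 + 0.1271 * T, (-3.08 + 0.0877 * T) / 1000)
    K2 *= pf(-15.82 - 0.0219 * T, (1.13 - 0.1475 * T) / 1000)
    KB *= pf(-29.48 + 0.1622 * T + 0.002608 * T * T, -2.84 / 1000)
    KW *= pf(-20.02 + 0.1119 * T - 0.001409 * T * T, (-5.13 + 0.0794 * T) / 1000)
    KF *= pf(-9.78 - 0.009 * T - 0.000942 * T * T, (-3.91 + 0.054 * T) / 1000)
    KS *= pf(-18.03 + 0.0466 * T + 0.000316 * T * T, (-4.53 + 0.09 * T) / 1000)
    KP1 *= pf(-14.51 + 0.1211 * T - 0.000321 * T * T, (-2.67 + 0.0427 * T) / 1000)
    KP2 *= pf(-23.12 + 0.1758 * T - 0.002647 * T * T, (-5.15 + 0.09 * T) / 1000)
    KP3 *= pf(-26.57 + 0.202 * T - 0.003042 * T * T, (-4.08 + 0.0714 * T) / 1000)
    KSi *= pf(-29.48 + 0.1622 * T + 0.002608 * T * T, -2.84 / 1000)

    sws2tot = (1 + TS / KS) / (1 + TS / KS + TF / KF)
    free2tot = 1 + TS / KS
    for_tot = dict(K1=K1 * sws2tot, K2=K2 * sws2tot, KB=KB * sws2tot,
                   KW=KW * sws2tot, KP1=KP1 * sws2tot, KP2=KP2 * sws2tot,
                   KP3=KP3 * sws2tot, KSi=KSi * sws2tot)

    tk100 = TK / 100.0
    K0 = math.exp(-60.2409 + 93.4517 / tk100 + 23.3585 * math.log(tk100)
                  + S * (0.023517 - 0.023656 * tk100 + 0.0047036 * tk100 ** 2))
    Delta = 57.7 - 0.118 * TK
    b = -1636.75 + 12.0408 * TK - 0.0327957 * TK ** 2 + 3.16528e-5 * TK ** 3
    fugfac = math.exp((b + 2 * Delta) * 1.01325 / RT)

    return dict(K0=K0, KS=KS, KF=KF, TB=TB, TS=TS, TF=TF,
                free2tot=free2tot, fugfac=fugfac, **for_tot)


def alkalinity(ph, dic, k, TP, TSi):
    """TA (mol/kg) from total-scale pH and DIC (mol/kg)."""
    H = 10.0 ** (-ph)
    denom = H * H + k["K1"] * H + k["K1"] * k["K2"]
    calk = dic * k["K1"] * (H + 2 * k["K2"]) / denom
    balk = k["TB"] * k["KB"] / (k["KB"] + H)
    oh = k["KW"] / H
    hfree = H / k["free2tot"]
    hso4 = k["TS"] / (1 + k["KS"] / hfree)
    hf = k["TF"] / (1 + k["KF"] / hfree)
    ptop = k["KP1"] * k["KP2"] * H + 2 * k["KP1"] * k["KP2"] * k["KP3"] - H ** 3
    pbot = H ** 3 + k["KP1"] * H ** 2 + k["KP1"] * k["KP2"] * H + k["KP1"] * k["KP2"] * k["KP3"]
    palk = TP * ptop / pbot
    sialk = TSi * k["KSi"] / (k["KSi"] + H)
    return calk + balk + oh + palk + sialk - hfree - hso4 - hf


def solve_dic_ta(dic, ta, T, S, P, sil, phos):
    k = constants(T, S, P)
    TP, TSi = phos * 1e-6, sil * 1e-6
    ph = brentq(lambda p: alkalinity(p, dic * 1e-6, k, TP, TSi) - ta * 1e-6,
                3.0, 12.0, xtol=1e-12)
    H = 10.0 ** (-ph)
    co2 = dic * 1e-6 * H * H / (H * H + k["K1"] * H + k["K1"] * k["K2"])
    pco2 = co2 / k["K0"] / k["fugfac"] * 1e6
    return ph, pco2


def solve_ph_ta(ph, ta, T, S, P, sil, phos):
    k = constants(T, S, P)
    TP, TSi = phos * 1e-6, sil * 1e-6
    dic = brentq(lambda d: alkalinity(ph, d, k, TP, TSi) - ta * 1e-6, 0.0, 0.02,
                 xtol=1e-15)
    H = 10.0 ** (-ph)
    co2 = dic * H * H / (H * H + k["K1"] * H + k["K1"] * k["K2"])
    pco2 = co2 / k["K0"] / k["fugfac"] * 1e6
    return dic * 1e6, pco2


def main(out):
    rng = np.random.default_rng(20260301)
    n = 100
    # Latin hypercube over oceanic ranges
    u = (rng.permuted(np.tile(np.arange(n), (6, 1)), axis=1).T + rng.random((n, 6))) / n
    ph = 7.2 + u[:, 0] * (8.3 - 7.2)
    ta = 2150 + u[:, 1] * (2450 - 2150)
    T = -1.5 + u[:, 2] * (26 - -1.5)
    S = 30 + u[:, 3] * (37 - 30)
    P = u[:, 4] * 4000
    sil = u[:, 5] * 120
    phos = sil / 40.0
    rows = []
    for i in range(n):
        dic, pco2 = solve_ph_ta(ph[i], ta[i], T[i], S[i], P[i], sil[i], phos[i])
        ph_back, pco2_b = solve_dic_ta(dic, ta[i], T[i], S[i], P[i], sil[i], phos[i])
        assert abs(ph_back - ph[i]) < 1e-8
        rows.append((ph[i], ta[i], T[i], S[i], P[i], sil[i], phos[i], dic, pco2))
    with open(out, "w") as fh:
        fh.write("ph,ta,temp,sal,pres,silicate,phosphate,dic,pco2\n")
        for r in rows:
            fh.write(",".join("%.10g" % v for v in r) + "\n")
    print("wrote", out)
    # pinned states quoted individually in the test suite
    ph25, pco2 = solve_dic_ta(2200.0, 2350.0, 25.0, 35.0, 0.0, 0.0, 0.0)
    print("dic2200_ta2350_25C_0dbar: ph=%.8f pco2=%.6f" % (ph25, pco2))
    dic, pco2 = solve_ph_ta(8.1, 2300.0, 2.0, 34.0, 0.0, 50.0, 1.5)
    print("ph8.1_ta2300_2C: dic=%.6f pco2=%.6f" % (dic, pco2))


if __name__ == "__main__":
    main(sys.argv[1] if len(sys.argv) > 1 else "carbonate_oracle.csv")
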