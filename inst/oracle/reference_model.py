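#!/usr/bin/env python
"""Independent reference implementation of the quiescence-proliferation ODE
model (synthetic reference: transcribed separately from the R package, from
the same documented equation set) used for cross-implementation validation.

Reads a key = value parameter file, integrates the wild-type stimulation
protocol (settle to the quiescent state at S = 0, then switch to the file's
S), and writes an XPPAUT-style whitespace-delimited .dat file (time column
followed by one column per species) plus a .names sidecar.

usage: reference_model.py PARAMS_CFG OUT_DAT [T_END] [DT]
"""
import sys

import numpy as np
from scipy.integrate import solve_ivp

SPECIES = [
    "Myc", "CycD", "CycDCKI", "CycE", "CycECKI", "CycA", "CycACKI",
    "CKI", "E2F", "Rb", "RbP", "RbPP", "RbE2F", "RbPE2F",
    "Cdh1", "Cdh1P", "Emi1", "Emi1Cdh1", "Ubl",
]


def read_params(path):
    out = {}
    with open(path) as fh:
        for line in fh:
            line = line.split("#", 1)[0].strip()
            if not line:
                continue
            key, val = line.split("=", 1)
            out[key.strip()] = float(val)
    return out


def rhs(t, y, p):
    s = dict(zip(SPECIES, y))
    mm = lambda x, J: x / (J + x)

    VD = s["CycD"]
    VE = p["e_cdk2"] * s["CycE"]
    VA = p["e_cdk2"] * s["CycA"]
    hE = s["E2F"] / (p["J_e2f"] + s["E2F"])

    dcki = p["k_dcki"] + p["k_dckiu"] * s["Ubl"] * (VE + VA)
    ddE = p["k_dcyce"] + p["k_dcycea"] * VA
    ddA = p["k_dcyca"] + p["k_dcycac"] * s["Cdh1"]
    dde2f = p["k_de2f"] + p["k_de2fa"] * VA
    demi = p["k_demi1"] + p["k_demi1c"] * s["Cdh1"]

    pm_R = p["k_pprbd"] * VD * mm(s["Rb"], p["J_prb"])
    pm_RE = p["k_pprbd"] * VD * mm(s["RbE2F"], p["J_prb"])
    ph_RP = p["k_pprbe"] * (VE + VA) * mm(s["RbP"], p["J_prb"])
    ph_RPE = p["k_pprbe"] * (VE + VA) * mm(s["RbPE2F"], p["J_prb"])
    pu_R = p["k_pprbue"] * (VE + VA) * mm(s["Rb"], p["J_prb"])
    pu_RE = p["k_pprbue"] * (VE + VA) * mm(s["RbE2F"], p["J_prb"])
    dp_RPP = p["k_dprbp"] * mm(s["RbPP"], p["J_dprb"])
    dp_RP = p["k_dprbp"] * mm(s["RbP"], p["J_dprb"])
    dp_RPE = p["k_dprbp"] * mm(s["RbPE2F"], p["J_dprb"])

    a_cdh1 = p["k_acdh1"] * mm(s["Cdh1P"], p["J_acdh1"])
    i_cdh1 = (p["k_icdh1e"] * VE + p["k_icdh1a"] * VA) * mm(s["Cdh1"], p["J_icdh1"])

    b_cd = p["k_ascd"] * s["CycD"] * s["CKI"] - p["k_dscd"] * s["CycDCKI"]
    b_ce = p["k_asce"] * s["CycE"] * s["CKI"] - p["k_dsce"] * s["CycECKI"]
    b_ca = p["k_asca"] * s["CycA"] * s["CKI"] - p["k_dsca"] * s["CycACKI"]
    b_re = p["k_asre"] * s["E2F"] * s["Rb"] - p["k_dsre"] * s["RbE2F"]
    b_rpe = p["k_asre"] * s["E2F"] * s["RbP"] - p["k_dsre"] * s["RbPE2F"]
    b_ec = p["k_asec"] * s["Emi1"] * s["Cdh1"] - p["k_dsec"] * s["Emi1Cdh1"]

    d = {}
    d["Myc"] = p["k_smyc"] * p["S"] - p["k_dmyc"] * s["Myc"]
    d["CycD"] = (p["k_scycds"] * p["S"] + p["k_scycdm"] * s["Myc"]
                 - p["k_dcycd"] * s["CycD"] - b_cd + dcki * s["CycDCKI"])
    d["CycDCKI"] = b_cd - (p["k_dcycd"] + dcki) * s["CycDCKI"]
    d["CycE"] = (p["k_scyceb"] + p["k_scyce"] * hE + p["k_scycem"] * s["Myc"]
                 - ddE * s["CycE"] - b_ce + dcki * s["CycECKI"])
    d["CycECKI"] = b_ce - (ddE + dcki) * s["CycECKI"]
    d["CycA"] = p["k_scyca"] * hE - ddA * s["CycA"] - b_ca + dcki * s["CycACKI"]
    d["CycACKI"] = b_ca - (ddA + dcki) * s["CycACKI"]
    d["CKI"] = (p["k_scki"] - dcki * s["CKI"] - b_cd - b_ce - b_ca
                + p["k_dcycd"] * s["CycDCKI"] + ddE * s["CycECKI"]
                + ddA * s["CycACKI"])
    d["E2F"] = (p["k_se2fb"] + p["k_se2f"] * hE + p["k_se2fm"] * s["Myc"]
                - dde2f * s["E2F"] - b_re - b_rpe + ph_RPE + pu_RE)
    d["Rb"] = -pm_R - pu_R + dp_RP - b_re + dde2f * s["RbE2F"]
    d["RbP"] = pm_R - ph_RP + dp_RPP - dp_RP - b_rpe + dde2f * s["RbPE2F"]
    d["RbPP"] = ph_RP + pu_R + ph_RPE + pu_RE - dp_RPP
    d["RbE2F"] = b_re - pm_RE - pu_RE + dp_RPE - dde2f * s["RbE2F"]
    d["RbPE2F"] = b_rpe + pm_RE - ph_RPE - dp_RPE - dde2f * s["RbPE2F"]
    d["Cdh1"] = a_cdh1 - i_cdh1 - b_ec + demi * s["Emi1Cdh1"]
    d["Cdh1P"] = i_cdh1 - a_cdh1
    d["Emi1"] = p["k_semi1"] * hE - demi * s["Emi1"] - b_ec
    d["Emi1Cdh1"] = b_ec - demi * s["Emi1Cdh1"]
    d["Ubl"] = p["k_subl"] - (p["k_dubl"] + p["k_dublc"] * s["Cdh1"]) * s["Ubl"]
    return [d[k] for k in SPECIES]


def main(argv):
    cfg, out = argv[0], argv[1]
    t_end = float(argv[2]) if len(argv) > 2 else 60.0
    dt = float(argv[3]) if len(argv) > 3 else 0.25
    p = read_params(cfg)

    # settle to quiescence at S = 0
    p0 = dict(p, S=0.0)
    y0 = np.zeros(len(SPECIES))
    y0[SPECIES.index("Rb")] = p["Rb_total"]
    y0[SPECIES.index("Cdh1")] = p["Cdh1_total"]
    y0[SPECIES.index("CKI")] = p["k_scki"] / max(p["k_dcki"], 1e-8)
    settle = solve_ivp(rhs, (0, 500), y0, args=(p0,), method="LSODA",
                       rtol=1e-8, atol=1e-10, dense_output=False)
    yq = settle.y[:, -1]

    # stimulate with the file's mitogen level
    tt = np.arange(0, t_end + dt / 2, dt)
    sol = solve_ivp(rhs, (0, t_end), yq, args=(p,), method="LSODA",
                    t_eval=tt, rtol=1e-8, atol=1e-10)
    tab = np.column_stack([sol.t, sol.y.T])
    np.savetxt(out, tab, fmt="%.10g")
    with open(out + ".names", "w") as fh:
        fh.write("\n".join(SPECIES) + "\n")


if __name__ == "__main__":
    main(sys.argv[1:])
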