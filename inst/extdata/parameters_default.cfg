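# model parameter set (concentrations in a.u., rates in 1/h)
# sha: 21e73406
S          =                  1
k_smyc     =                 25
k_dmyc     =                0.5
k_scycds   = 0.040000000000000001
k_scycdm   =              0.002
k_dcycd    = 0.050000000000000003
k_scyceb   = 0.012999999999999999
k_scyce    = 0.14999999999999999
k_scycem   =                  0
k_dcyce    = 0.20000000000000001
k_dcycea   =                0.5
k_scyca    = 0.14999999999999999
k_dcyca    = 0.10000000000000001
k_dcycac   =                1.5
k_se2fb    = 0.080000000000000002
k_se2f     = 0.050000000000000003
k_se2fm    =                  0
k_de2f     = 0.10000000000000001
k_de2fa    = 0.10000000000000001
J_e2f      = 0.10000000000000001
k_scki     = 0.074999999999999997
k_dcki     = 0.14999999999999999
k_dckiu    =                  3
k_semi1    = 0.90000000000000002
k_demi1    = 0.26000000000000001
k_demi1c   = 3.3999999999999999
k_subl     =                  2
k_dubl     =                  2
k_dublc    =                 50
k_acdh1    = 0.59999999999999998
J_acdh1    = 0.29999999999999999
k_icdh1e   =                1.3
k_icdh1a   = 0.29999999999999999
J_icdh1    = 0.29999999999999999
k_pprbd    =                  2
k_pprbe    =                  2
k_pprbue   = 0.34999999999999998
k_dprbp    = 0.20000000000000001
J_prb      =                0.5
J_dprb     =                0.5
k_asre     =                100
k_dsre     = 0.10000000000000001
k_ascd     =                 50
k_dscd     =                0.5
k_asce     =                 50
k_dsce     =                0.5
k_asca     =                 50
k_dsca     =                0.5
k_asec     =                 50
k_dsec     =                0.5
e_cdk2     =                  1
Rb_total   =                1.5
CKI_total  =                0.5
Cdh1_total =                  1
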