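# Default synthetic-cohort calibration: a 103-patient metastatic NSCLC cohort
# mirroring the motivating study's printed structure and effect sizes.
counts:
  n_total: 103
  n_ici: 81
  n_egfr: 19
  n_alk: 13
  n_wt: 71
  n_dcb: 30
  n_nondcb: 49
  n_earlycensor: 2
  n_ici_egfr: 10
  n_ici_alk: 4
  n_favorable: 11
  n_favorable_dcb: 9
survival:
  hr_pfs_dcb: 0.15          # PFS hazard ratio, DCB vs non-DCB
  hr_os_dcb: 0.11           # OS hazard ratio, DCB vs non-DCB
  hr_tncd8: 1.79            # multivariable HR, low vs high TN CD8 density
  lambda_pfs: 0.006667      # baseline PFS hazard, 1/day (median ~104 d)
  lambda_os: 0.0025         # baseline OS hazard, 1/day
  lambda_pfs_nonici: 0.005556
  lambda_os_nonici: 0.002222
  censor_days: 1095         # administrative censoring horizon
  dcb_boundary: 365         # 1 year
  responder_cd8_logodds: 0.0   # responder sampling tilt toward high TN CD8
                               # (the favorable-TME planting already couples
                               #  response to the high-CD8 phenotype)
geometry:
  field_width: 1800         # um
  field_height: 1800
  n_nests: 2
  nest_radius_median: 400   # um
  nest_radius_sdlog: 0.1
  nest_radius_min: 310
  nest_radius_max: 450
  nest_jitter: 60
cells:
  cancer_density: 750       # cells/mm^2 inside nests
  stromal_density: 300      # CAF + other stromal cells/mm^2 in stroma
  densities:                # per-subset log-normal medians (cells/mm^2)
    cd8:  {tn: 250, isa: 200, sdlog: 0.45}
    cd8_favorable: {tn: 450, isa: 250, sdlog: 0.3}
    treg: {tn: 40,  isa: 60,  sdlog: 0.5}
    th1:  {tn: 30,  isa: 40,  sdlog: 0.5}
    cd4:  {tn: 80,  isa: 100, sdlog: 0.5}
    nk:   {tn: 20,  isa: 30,  sdlog: 0.5}
    nkt:  {tn: 15,  isa: 20,  sdlog: 0.5}
    b:    {tn: 20,  isa: 60,  sdlog: 0.5}
    tam:  {tn: 100, isa: 120, sdlog: 0.4}
    dc:   {tn: 25,  isa: 40,  sdlog: 0.5}
    mdsc: {tn: 30,  isa: 40,  sdlog: 0.5}
    leukocyte_other: {tn: 20, isa: 30, sdlog: 0.5}
  trm_frac:                 # Trm-like fraction of CD8 TILs (beta)
    other:     {a: 12, b: 28}
    favorable: {a: 28, b: 12}
markers:                    # phenotype positivity targets (beta a/b)
  ki67_trm:
    other:     {a: 5,  b: 45}
    favorable: {a: 26, b: 14}
  cd206_tam:
    other:     {a: 12, b: 12}
    favorable: {a: 4,  b: 36}
  fap_stromal:
    other:     {a: 18, b: 22}
    favorable: {a: 8, b: 32}
  cd163_tam: {a: 8, b: 12}
  m1_frac: 0.5
  ki67_cd8t: {a: 2, b: 18}
  ki67_cancer: {a: 6, b: 14}
  pd1_trm: {a: 12, b: 8}
  pd1_cd8t: {a: 8, b: 12}
  pd1_treg: {a: 6, b: 14}
  pd1_cd4: {a: 4, b: 16}
  lag3_trm: {a: 7, b: 13}
  tim3_trm: {a: 8, b: 12}
  tigit_trm: {a: 10, b: 10}
  lag3_cd8t: {a: 3, b: 17}
  tim3_cd8t: {a: 4, b: 16}
  tigit_cd8t: {a: 6, b: 14}
  gzmb_cd8: {a: 6, b: 14}
  tbet_nk: {a: 10, b: 10}
  cd73_cancer_wt: {a: 2, b: 8}
  cd73_cancer_driver: {a: 5, b: 5}
  pdl1_tam: {a: 6, b: 14}
intensity:
  sigma: 0.25               # log-normal component SD (log intensity units)
  offset: 3                 # component centres at threshold * exp(+/- offset*sigma)
expression:
  n_genes: 726
  n_egfr: 9
  n_wt: 18
  noise_sd: 1.0
  effects:                  # per-gene log2 shifts in EGFR-mutant tumors
    NT5E: 2.0
    MRC1: 1.5
    VEGFB: 1.0
    TGFB2: 1.0
    TGFBR2: 1.0
  set_effects:              # per-gene-set log2 shifts in EGFR-mutant tumors
    mapk: 0.8
    nfkb: 0.8
    autophagy: 0.8
    angiogenesis: 0.6
    tgf_beta: 0.6
seed: 42
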