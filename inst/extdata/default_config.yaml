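seed: 1
cohort:
  n_carcasses: 60
  traits:
  - trait: pH
    muscle: LTL
    mean: 5.56
    sd: 0.108443533693808
    lower: 5.33
    upper: 5.88
  - trait: pH
    muscle: SM
    mean: 5.65
    sd: 0.139427400463467
    lower: 5.46
    upper: 5.99
  - trait: collagen_mg_g
    muscle: LTL
    mean: 4.56
    sd: 0.565455568546283
    lower: 3.51
    upper: 5.57
  - trait: collagen_mg_g
    muscle: SM
    mean: 4.73
    sd: 0.836564402780802
    lower: 3.21
    upper: 8.51
  - trait: collagen_solubility_pct
    muscle: LTL
    mean: 10.199999999999999
    sd: 1.998459406643027
    lower: 6.13
    upper: 18.5
  - trait: collagen_solubility_pct
    muscle: SM
    mean: 9.19
    sd: 1.851286039487145
    lower: 5.78
    upper: 13.4
  - trait: imf_pct
    muscle: LTL
    mean: 1.04
    sd: 0.395044301313156
    lower: 0.443
    upper: 2.25
  - trait: imf_pct
    muscle: SM
    mean: 1.38
    sd: 0.503487835006964
    lower: 0.579
    upper: 2.84
  cross_muscle_r2:
    pH: 0.273
    collagen_mg_g: 0.214
    collagen_solubility_pct: 0.104
    imf_pct: 0.044
  nmr_link:
    p_2f:
      intercept: 0.05
      coef_imf: 0.004679245283019
      coef_ph: -0.027333333333333
      resid_sd: 0.0041
    p_21:
      intercept: 0.85
      coef_imf: 0.0
      coef_ph: 0.0
      resid_sd: 0.033
    p_22:
      intercept: 0.1
      coef_imf: 0.0
      coef_ph: 0.0
      resid_sd: 0.033
    t_21_ms:
      intercept: 40.0
      coef_imf: 0.0
      coef_ph: 0.0
      resid_sd: 3.0
    t_22_ms:
      intercept: 150.0
      coef_imf: 0.0
      coef_ph: 0.0
      resid_sd: 10.0
  nirs_link:
    intercept: 0.59
    slope: 0.51394422310757
    between_sd: 0.38
    replicate_sd: 0.3
  sensory:
    slopes:
      tenderness:
        pH: 14.1
        collagen_mg_g: -3.86
        collagen_solubility_pct: -0.79
        imf_pct: 0.4
      juiciness:
        pH: 12.6
        collagen_mg_g: -2.76
        collagen_solubility_pct: -0.83
        imf_pct: 0.88
      flavor:
        pH: 11.699999999999999
        collagen_mg_g: -2.6
        collagen_solubility_pct: -0.68
        imf_pct: 2.91
      overall:
        pH: 14.199999999999999
        collagen_mg_g: -3.42
        collagen_solubility_pct: -0.69
        imf_pct: 1.58
    muscle_means:
      LTL:
        tenderness: 48.799999999999997
        juiciness: 48.100000000000001
        flavor: 52.0
        overall: 52.0
      SM:
        tenderness: 51.700000000000003
        juiciness: 54.100000000000001
        flavor: 54.0
        overall: 54.700000000000003
    sd_session: 3.0
    sd_participant: 10.0
    sd_carcass: 5.0
    sd_residual: 15.0
    off_flavor_prob:
      LTL: 0.004
      SM: 0.008
    purchase_success:
      LTL: 0.298
      SM: 0.351
    quality_success:
      LTL: 0.284
      SM: 0.318
    sd_session_logit: 0.2
    sd_participant_logit: 0.5
    sd_carcass_logit: 0.3
    truncate: yes
    n_sessions: 9
    participants_per_session: 20
    consumers_per_sample: 10
acquisition:
  n_echoes: 2000
  echo_spacing_ms: 0.3
  polarization_delay_ms: 750.0
  points_per_echo: 8
  noise_sd: 40.0
  snr_threshold: 200.0
  max_scans: 256
fit:
  fixed_t2f_ms: 10.0
  t21_bounds:
  - 10.0
  - 100.0
  t22_bounds:
  - 100.0
  - 2000.0
  n_starts_grid: 4
  rel_tol: 1.0e-10
  max_iter: 500
  collapse_rel_tol: 0.05
  seed: 1
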