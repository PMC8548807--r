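wavelength:
  start: 300.0
  stop: 700.0
  step: 1.0
depth:
  length_um: 450.0
  dz_um: 5.0
pigments:
- receptor: R1
  lmax_R: 515.0
  lmax_M: 495.0
  alpha_R: 6.0
  alpha_M: 7.5
- receptor: R2
  lmax_R: 515.0
  lmax_M: 495.0
  alpha_R: 6.0
  alpha_M: 7.5
- receptor: R3
  lmax_R: 545.0
  lmax_M: 505.0
  alpha_R: 6.0
  alpha_M: 7.5
- receptor: R4
  lmax_R: 545.0
  lmax_M: 505.0
  alpha_R: 6.0
  alpha_M: 7.5
- receptor: R5
  lmax_R: 545.0
  lmax_M: 505.0
  alpha_R: 6.0
  alpha_M: 7.5
- receptor: R6
  lmax_R: 545.0
  lmax_M: 505.0
  alpha_R: 6.0
  alpha_M: 7.5
- receptor: R7
  lmax_R: 545.0
  lmax_M: 505.0
  alpha_R: 6.0
  alpha_M: 7.5
- receptor: R8
  lmax_R: 545.0
  lmax_M: 505.0
  alpha_R: 6.0
  alpha_M: 7.5
- receptor: R9
  lmax_R: 545.0
  lmax_M: 505.0
  alpha_R: 6.0
  alpha_M: 7.5
rho_profile:
  r12_frac: 0.15
  r12_zmax: 250.0
  r34_frac_distal: 0.2
  r34_frac_mid: 0.25
  r9_zmin: 400.0
  r9_zmax: 450.0
screening:
  lambda_half: 600.0
  steepness: 0.05
  alpha_S: 35.0
  z_min: 230.0
  z_max: 420.0
tapetum_reflectance: 1.0
beta_band: yes
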