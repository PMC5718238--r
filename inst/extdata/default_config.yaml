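geometry:
  cell_size_um: 5.0
  epidermis_thickness_um: 80.0
  melanin_fraction_epidermis: 0.05
  melanin_fraction_hair: 0.3
  follicle_top_depth_um: 200.0
  follicle_diameter_um: 200.0
  follicle_length_um: 2000.0
  domain_width_um: 3000.0
  domain_depth_um: 4000.0
optics:
  melanin_anchor_694_per_m: 30000.0
  melanin_exponent: 3.48
  blood_fraction_dermis: 0.005
  water_fraction:
    EPIDERMIS: 0.2
    DERMIS: 0.65
    HAIR: 0.1
  mus500_per_m:
    EPIDERMIS: 6600.0
    DERMIS: 3000.0
    HAIR: 4500.0
  f_rayleigh: 0.4
  b_mie: 0.9
  anisotropy_g: 0.789
spectrum:
  shape: blackbody
  cutoff_nm: 695.0
  temperature_K: 5500.0
  file: ~
beam:
  fluence_J_cm2: 10.0
  width_um: ~
transport:
  n_photons: 1000000.0
  seed: 2.0120906e+07
  residual: deposit
solver:
  dt_s: 5.0e-05
  t_end_s: ~
  t_extra_s: 0.03
  baseline_C: 35.0
  surface_bc: convective
  h_W_m2K: 10.0
  t_ambient_C: 20.0
  far_bc: fixed
  far_T_C: 35.0
comparison:
  categories:
  - FREE_DISCHARGE
  - SQUARE_PULSE
  - CLOSE_PULSE_STACK
  - SPACED_PULSE_STACK
  threshold_C: 70.0
probes:
  epidermal_depth_um: 20.0
  follicle_depth_um: 2000.0
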