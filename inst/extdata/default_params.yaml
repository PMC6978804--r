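# Default model and control parameters for the rat locomotion model.
# Units are carried in field names (mass_g, length_mm, moi_gmm2, Fmax_N,
# MA_mm, angles in degrees) and converted to SI on load.

skeleton:
  gravity_ms2: 9.81
  links:
    trunk:        {mass_g: 99.8, length_mm: 93.0, moi_gmm2: 141000, com_frac: 0.5}
    brachium:     {mass_g: 1.6,  length_mm: 16.1, moi_gmm2: 57,     com_frac: 0.5}
    antebrachium: {mass_g: 1.6,  length_mm: 19.0, moi_gmm2: 53,     com_frac: 0.5}
    thigh:        {mass_g: 5.2,  length_mm: 18.5, moi_gmm2: 573,    com_frac: 0.5}
    shank:        {mass_g: 2.8,  length_mm: 27.2, moi_gmm2: 262,    com_frac: 0.5}
    foot:         {mass_g: 1.5,  length_mm: 17.7, moi_gmm2: 75,     com_frac: 0.5}

  # anatomical joint-range stops (hard stop at the straight joint)
  joint_limits: {min_deg: 10.0, max_deg: 180.0, k_Nm_per_rad: 0.5, c_Nm_s_per_rad: 0.002}

contact:
  k_vert_Nm: 1000.0
  c_vert_Nsm: 5.0
  k_horiz_Nm: 1000.0
  c_horiz_Nsm: 5.0
  mu_friction: 0.9
  ground_z_m: 0.0

muscle_geometry:
  neutral_posture_deg: {shoulder: 60, elbow: 85, hip: 70, knee: 90, ankle: 100}
  neutral_length: {uniarticular: 0.85, biarticular: 0.75}
  velocity_norm_lmax_per_s: 1.8
  deg_per_pct_default: 2.0

muscle_curves:
  fl_width: 0.3
  fv_vmax: 3.0
  fv_shape: 0.4
  fv_ecc_a: 7.56
  fv_ecc_b: 3.75
  fv_ecc_cap: 1.5
  fp_scale: 0.02
  fp_rate: 6.0
  fp_damp: 0.0

muscles:
  tau_act_s: 0.011
  tau_deact_s: 0.018
  table:
    SSP:  {limb: fore, Fmax_N: 11.1,
           joints: {shoulder: {action: extensor, MA_mm: 3.6}}}
    SPD:  {limb: fore, Fmax_N: 9.8,
           joints: {shoulder: {action: flexor, MA_mm: 5.3}}}
    BR:   {limb: fore, Fmax_N: 5.1,
           joints: {elbow: {action: flexor, MA_mm: 3.6}}}
    TRIL: {limb: fore, Fmax_N: 11.5,
           joints: {elbow: {action: extensor, MA_mm: 5.9}}}
    BIC:  {limb: fore, Fmax_N: 7.7,
           joints: {shoulder: {action: extensor, MA_mm: 2.4, deg_per_pct: 4.5},
                    elbow: {action: flexor, MA_mm: 4.0}}}
    TRI:  {limb: fore, Fmax_N: 23.2,
           joints: {shoulder: {action: flexor, MA_mm: 5.7},
                    elbow: {action: extensor, MA_mm: 5.9}}}
    IP:   {limb: hind, Fmax_N: 15.7,
           joints: {hip: {action: flexor, MA_mm: 4.5}}}
    GM:   {limb: hind, Fmax_N: 23.3,
           joints: {hip: {action: extensor, MA_mm: 2.3}}}
    VL:   {limb: hind, Fmax_N: 24.0,
           joints: {knee: {action: extensor, MA_mm: 3.2}}}
    TA:   {limb: hind, Fmax_N: 4.1,
           joints: {ankle: {action: flexor, MA_mm: 5.1}}}
    SO:   {limb: hind, Fmax_N: 3.5,
           joints: {ankle: {action: extensor, MA_mm: 6.0}}}
    BF:   {limb: hind, Fmax_N: 3.1,
           joints: {hip: {action: extensor, MA_mm: 2.5},
                    knee: {action: flexor, MA_mm: 12.5}}}
    GA:   {limb: hind, Fmax_N: 4.5,
           joints: {knee: {action: flexor, MA_mm: 4.2, deg_per_pct: 4.5},
                    ankle: {action: extensor, MA_mm: 6.0, deg_per_pct: 1.5}}}

control:
  K1: 20.0
  K2: 10.0
  T_fl_s: 0.10
  beta_hat: 0.62
  # pulse onset/end phases in units of pi
  Phi_hat_pi: [0.0, 0.40, 1.24, 1.42]
  Psi_hat_pi: [0.33, 0.89, 1.42, 1.71]
  weights:
    SSP:  {p1: 0.24, p4: 0.20}
    SPD:  {p2: 0.27, p3: 0.08}
    BR:   {p3: 0.09}
    TRIL: {p1: 0.47, p2: 0.57}
    BIC:  {p3: 0.17, p4: 0.08}
    TRI:  {p1: 0.27, p2: 0.56}
    IP:   {p3: 0.32, p4: 0.32}
    GM:   {p1: 0.61, p2: 0.25}
    VL:   {p1: 0.19, p2: 0.22}
    TA:   {p3: 0.45, p4: 0.06}
    SO:   {p1: 0.58, p2: 0.14}
    BF:   {p1: 0.22, p2: 0.12, p3: 0.09}
    GA:   {p1: 0.47, p2: 0.10}
  h0_shoulder_m: 0.033
  h0_hip_m: 0.054
  v0_ms: 0.4
  K_height: {BR: -2.07, TRIL: 2.07, VL: 12.4, TA: -12.4, SO: 12.4}
  D_height: {BR: -0.001, TRIL: 0.001, VL: 0.006, TA: -0.006, SO: 0.006}
  K_speed:  {SSP: -0.007, SPD: 0.007, IP: -0.052, GM: 0.052, TA: -0.026, SO: 0.026}
  alpha_shoulder_m: 0.01
  alpha_hip_m: 0.01
  alpha_speed_ms: -4.7
  tau_delay_ms: 15.0
  ramp_rate_per_cycle: 0.005

sim:
  # start-up assist: an external trunk height/pitch stabilizer active for
  # hold_s seconds, then faded linearly to zero over fade_s (the gait is
  # measured only on assist-free cycles)
  assist: {hold_s: 1.0, fade_s: 3.0, kz: 500.0, cz: 10.0, kp: 0.1, cp: 0.01,
           z_offset: 0.0, floor: 0.5}
  dt_s: 2.0e-5
  log_every: 50
  pitch_max_deg: 60.0
  height_fail_frac: 0.3
  qd_max: 1000.0
  discard_cycles: 5
  measure_cycles: 10
  beta_sweep: {min: 0.56, max: 0.68, step: 0.03}
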