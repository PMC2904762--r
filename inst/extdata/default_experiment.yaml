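conditions:
  low_noise_low_cost:
    noise: low
    cost: low
    mass_kg: 1.0
    dt_s: 0.01
    horizon_s: 1.0
    ball_speed_y_cm_s: 15.0
    process_noise_sd: 1.0
    error_weight: 1.0
    control_weight: 0.1
    hand_force_gain_N_per_cm: 10.0
    condition_label: low_noise_low_cost
  low_noise_high_cost:
    noise: low
    cost: high
    mass_kg: 1.0
    dt_s: 0.01
    horizon_s: 1.0
    ball_speed_y_cm_s: 15.0
    process_noise_sd: 1.0
    error_weight: 1.0
    control_weight: 0.3
    hand_force_gain_N_per_cm: 10.0
    condition_label: low_noise_high_cost
  high_noise_low_cost:
    noise: high
    cost: low
    mass_kg: 1.0
    dt_s: 0.01
    horizon_s: 1.0
    ball_speed_y_cm_s: 15.0
    process_noise_sd: 5.0
    error_weight: 1.0
    control_weight: 0.1
    hand_force_gain_N_per_cm: 50.0
    condition_label: high_noise_low_cost
  high_noise_high_cost:
    noise: high
    cost: high
    mass_kg: 1.0
    dt_s: 0.01
    horizon_s: 1.0
    ball_speed_y_cm_s: 15.0
    process_noise_sd: 5.0
    error_weight: 1.0
    control_weight: 0.3
    hand_force_gain_N_per_cm: 50.0
    condition_label: high_noise_high_cost
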