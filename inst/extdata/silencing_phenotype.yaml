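# Scenario emulating the reported giant-fibre-silencing phenotype:
# silencing removes the short take-off mode (weight 0.70 -> 0.02) without
# touching the reaction-time distribution, roughly halves the escape
# proportion during predation events, doubles per-fly consumption, and lets
# the damselfly approach closer before capture (end distance 1.8 mm vs
# 3.4 mm, i.e. beyond the ~40 degree retinal-size threshold only for the
# silenced arm).
name: silencing_phenotype
seed: 1
boundary_ms: 7
head_width_mm: 2.2
speed_split_threshold: 0.167
stimulus:
  r_over_v_ms: 10
  theta_onset_deg: 10
  theta_max_deg: 90
smoothing:
  butterworth_order: 2
  butterworth_cutoff_hz: 30
  savgol_window: 11
  savgol_polyorder: 3
ethograms:
  n: {control: 80, silenced: 29}
  control:
    takeoff_prob: 0.85
    reaction_mean_ms: 95
    reaction_sd_ms: 10
    short_mode_weight: 0.70
    short_meanlog: 1.5041
    short_sdlog: 0.15
    long_meanlog: 2.7081
    long_sdlog: 0.25
  silenced:
    takeoff_prob: 0.55
    reaction_mean_ms: 95
    reaction_sd_ms: 10
    short_mode_weight: 0.02
    short_meanlog: 1.5041
    short_sdlog: 0.15
    long_meanlog: 2.7081
    long_sdlog: 0.25
trials:
  n_trials: 15
  n_per_group: 100
  p_eaten: {control: 0.15, silenced: 0.30}
attacks:
  n_events: {control: 100, silenced: 100}
  speed_meanlog: -1.8326
  speed_sdlog: 0.45
  speed_min: 0.06
  speed_max: 0.6
  # silencing flattens the capture probability in speed (slope 0) instead of
  # shifting it: slow and fast attacks succeed about equally often
  capture_model:
    intercept: {control: -2.5, silenced: 0.2}
    slope: {control: 25, silenced: 0}
    ref_speed: 0.167
  end_distance_mm: {capture_control: 3.4, capture_silenced: 1.8, escape: 4.2}
  elevation_mean: 10
  elevation_sd: 8
  azimuth_mean: 45
  azimuth_sd: 25
  hover_distance: 30
  hover_duration: 100
  hover_jitter_sd: 0.2
  base_speed_frac: 0.35
  bump_width: 25
  peak_time_before_contact: 30
  onset_ramp_ms: 60
  digitization_noise_sd: 0.1
  frame_rate: 1000
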