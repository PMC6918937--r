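# Default fatigue trajectory for the synthetic EEG generator.
# One value per time point, T0 .. T4.
time_points: [T0, T1, T2, T3, T4]

# Multiplier on the slow rhythms (theta, alpha1, alpha2) relative to beta.
# Rises while fatigue builds, eases slightly once subjects disengage.
slow_fast_gain: [1.00, 1.25, 1.50, 1.45, 1.40]

# Weight of the single alpha1-band source shared by all channels
# (y = sqrt(1 - c) x + sqrt(c) s). Rises to T3, dips at T4.
alpha1_coupling: [0.10, 0.26, 0.37, 0.48, 0.30]

# Weight of the spatial (distance-decay) component of the alpha1 base
# correlation; 1 = fully spatially organized, 0 = spatially uniform.
# Decays to T3 (connectivity becomes diffuse), partially recovers at T4.
alpha1_structure: [1.00, 0.60, 0.35, 0.00, 0.55]

# Per-rhythm base amplitudes (standard deviations, arbitrary uV-like units).
band_amplitude:
  delta: 12
  theta: 8
  alpha1: 10
  alpha2: 7
  beta: 5

# Correlation decay length, in electrode-grid units.
spatial_decay: 1.5

# Apply the coupling/structure trajectory only in the task condition;
# the resting condition is held at the T0 (baseline) values.
task_only_coupling: true
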