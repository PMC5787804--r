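velocities:
- 50.0
- 138.0
- 381.0
- 1051.0
- 2899.0
- 8000.0
curves_per_velocity: 50
p_bind: 0.13
p_nonspecific: 0.05
k_off: 0.1
x_beta: 0.5
contour_length: 10.0
kuhn_length: 0.7
k_c: 30.0
noise_sigma: 5.0
tilt: 0.0
sample_step: 0.2
max_distance: 30.0
force_limit: 100.0
temperature: 298.0
seed: 7
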