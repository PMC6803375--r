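# Example synthetic-embryo configuration (small two-cycle movie).
field_dim: {z: 8, "y": 192, x: 192}
spacing_um: {z: 3, "y": 0.6, x: 0.6}
frame_interval_s: 30
n_frames: 16
n_initial: 4
cycle_length_s: 300
mitosis_duration_s: 60
nucleus_radius_um: 5
radius_shrink: 0.8
motion_sd_um: 0.2
embryo_radius_frac: 0.25
initial_stage_count: 64
background: 50
noise: {poisson: true, gain: 1.0, gaussian_sd: 4}
seed: 3
channels:
  - name: marker
    nc: {type: constant, value: 4}
    cytoplasm_level: 200
  - name: signal
    nc: {type: ramp, from: 1, to: 3, t_start_s: 0, t_end_s: 450}
    cytoplasm_level: 200
    foci: {n_foci: 2, onset_time_s: 0, peak_time_s: 240, amplitude: 5, sigma_um: 0.6}
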