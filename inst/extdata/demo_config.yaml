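# Small demonstration pipeline configuration (about half a minute to run).
seed: 7
duration_s: 180
scenario:
  width_px: 160
  height_px: 128
  fps: 5
  mouse_radius_px: 12
model:
  mean_wake_bout_s: 60
  mean_sleep_bout_s: 90
n_patches_per_class: 60
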