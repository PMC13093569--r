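# Example pillarbeat run configuration (see ?run_config).
# Unknown keys are rejected; frame_rate_hz has no default because image
# containers carry no timing metadata.
input: recording.tif
output_dir: pillarbeat_out
pixel_scale_um: 3.79
frame_rate_hz: 30
pacing_rate_hz: 1.0
geometry:
  length_m: 12.0e-3
  youngs_modulus_pa: 1.7e+6
  diameter_m: 1.2e-3
tracking:
  mode: cumulative
seed: 1
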