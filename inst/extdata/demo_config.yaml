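# Demo run: a small synthetic field under the standard neuromodulation
# condition (1 MHz, 10 Hz PRF, 50 ms pulses, 0.5 s trains every 30 s) with a
# visual and a combined visual+ultrasound block, so every pipeline stage
# (classification, modulation subgrouping, exposure) is exercised.
seed: 5
out_dir: demo_out
write_traces: false
population:
  n_neurons: 80
  us_responder_fraction: 0.0375
  us_response_prob: 0.9
  visual_responder_fraction: 0.15
protocols:
  - modality: visual
    peak_negative_pressure: 0
    n_trials: 4
  - modality: combined
    peak_negative_pressure: 315
    n_trials: 4
analysis:
  excited_threshold: 2
  un_rate_threshold: 0.30
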