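{
  "genome": {"length_bp": 5e6, "ori_pos": 0, "ter_pos": 2.5e6},
  "attachment": {"n_scaffold": 475, "n_envelope": 0, "layout": "loop_rosette"},
  "breaks": {"b": 100},
  "scenarios": [
    {"strain": "WT", "a": 475, "b_treated": 100, "background": 0.02,
     "atp_A": 0.09, "atp_k": 0.0406, "transcription_share_true": 0.6667}
  ],
  "times": [0, 15, 30, 45, 60, 75, 90, 105],
  "n_replicates": 3,
  "noise_sd": 0.01,
  "seed": 1,
  "mc_replicates": 10000,
  "classical_loops": 50,
  "gel": {"smear_min": 2e4, "cz_min": 2e6},
  "treatment_duration": 45,
  "outdir": "results"
}
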