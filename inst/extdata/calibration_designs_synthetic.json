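{
  "note": "Synthetic stand-in for the pooled in vitro calibration set: 9 invented study designs totalling 43 observation slots, spanning constant (CG, 15-25 mM), oscillating (OG, 24-h half-period) and post-normalization (NG) sampling from hours to weeks. The per-study designs of the real pooled dataset were never published; these are frozen here so generated datasets are reproducible.",
  "designs": [
    {"id": "study01", "protocol": "cg:15mM:14d", "times_h": [24, 48, 168, 336], "n_replicates": 1},
    {"id": "study02", "protocol": "cg:20mM:14d", "times_h": [24, 48, 168, 336], "n_replicates": 1},
    {"id": "study03", "protocol": "cg:25mM:7d", "times_h": [6, 24, 48, 96, 168], "n_replicates": 1},
    {"id": "study04", "protocol": "cg:20mM:2d", "times_h": [6, 12, 24, 48], "n_replicates": 1},
    {"id": "study05", "protocol": "og:5-20mM:24h:14d", "times_h": [48, 96, 168, 240, 336], "n_replicates": 1},
    {"id": "study06", "protocol": "og:5-25mM:24h:7d", "times_h": [48, 96, 144, 168], "n_replicates": 1},
    {"id": "study07", "protocol": "cg:20mM:14d+ng:5mM:21d", "times_h": [24, 336, 504, 672, 840], "n_replicates": 1},
    {"id": "study08", "protocol": "og:5-20mM:24h:14d+ng:5mM:21d", "times_h": [336, 504, 672, 840], "n_replicates": 1},
    {"id": "study09", "protocol": "cg:25mM:14d+ng:5mM:56d", "times_h": [24, 168, 336, 504, 672, 840, 1008, 1176], "n_replicates": 1}
  ]
}
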