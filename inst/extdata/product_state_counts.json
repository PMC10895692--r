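{
  "_note": "Published worked example: numbers of completed trajectories per product energy state (302 completed of 310 launched).",
  "n_completed": 302,
  "counts": {"S0": 180, "S1": 52, "S2": 0, "S3": 0, "T1": 70, "T2": 0}
}
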