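{
  "_note": "Feature ranges behind the published endpoint-subrange (RLSE) percentages. omega0_1234 bounds are the printed values; the omega0_3456 global range follows from the printed 20.0% subrange; the 'additional' entries are SYNTHETIC range reconstructions chosen to encode the published percentages exactly (the underlying bounds were not printed).",
  "omega0_1234": {
    "global": [-3.0, 2.0],
    "subranges": {"T1": [-3.0, 1.5], "S0": [-2.0, 2.0], "S1": [-2.5, 1.0]},
    "quoted_rlse": {"S0_lower": 20.0, "S1_upper": 20.0}
  },
  "omega0_3456": {
    "global": [-2.0, 3.0],
    "subranges": {"T1": [-1.0, 3.0]},
    "quoted_rlse": {"T1_lower": 20.0}
  },
  "additional": [
    {"name": "v0_12_lower", "global": [0, 8], "subrange": [2, 8], "end": "lower", "rlse": 25.0},
    {"name": "v0_12_upper", "global": [0, 8], "subrange": [0, 7], "end": "upper", "rlse": 12.5},
    {"name": "v0_34_lower", "global": [0, 13], "subrange": [3, 13], "end": "lower", "rlse": 23.1},
    {"name": "v0_34_upper", "global": [0, 13], "subrange": [0, 10], "end": "upper", "rlse": 23.1},
    {"name": "v0_56_upper", "global": [0, 3], "subrange": [0, 2], "end": "upper", "rlse": 33.3}
  ]
}
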