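{
  "comment": "8-node chest-clinic benchmark network; canonical CPTs. State 0 = yes, state 1 = no. CPT rows are parent configurations in mixed-radix order, lowest parent index most significant. Integer node labels used by path-constraint lists are 1-based positions in the variables list: 1=asia, 2=tub, 3=smoke, 4=lung, 5=bronc, 6=either, 7=xray, 8=dysp.",
  "variables": [
    {"name": "asia",   "cardinality": 2},
    {"name": "tub",    "cardinality": 2},
    {"name": "smoke",  "cardinality": 2},
    {"name": "lung",   "cardinality": 2},
    {"name": "bronc",  "cardinality": 2},
    {"name": "either", "cardinality": 2},
    {"name": "xray",   "cardinality": 2},
    {"name": "dysp",   "cardinality": 2}
  ],
  "edges": [
    ["asia", "tub"],
    ["smoke", "lung"],
    ["smoke", "bronc"],
    ["tub", "either"],
    ["lung", "either"],
    ["either", "xray"],
    ["bronc", "dysp"],
    ["either", "dysp"]
  ],
  "cpts": {
    "asia":   [[0.01, 0.99]],
    "tub":    [[0.05, 0.95], [0.01, 0.99]],
    "smoke":  [[0.5, 0.5]],
    "lung":   [[0.1, 0.9], [0.01, 0.99]],
    "bronc":  [[0.6, 0.4], [0.3, 0.7]],
    "either": [[1.0, 0.0], [1.0, 0.0], [1.0, 0.0], [0.0, 1.0]],
    "xray":   [[0.98, 0.02], [0.05, 0.95]],
    "dysp":   [[0.9, 0.1], [0.8, 0.2], [0.7, 0.3], [0.1, 0.9]]
  }
}
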