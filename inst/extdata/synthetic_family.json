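{
  "topology": "(((A,B),(C,D)),(E,F));",
  "substitutions": {
    "A+B+C+D": 40,
    "A+B": 30,
    "A": 5,
    "B": 5,
    "C+D": 30,
    "C": 5,
    "D": 5,
    "E+F": 60,
    "E": 20,
    "F": 20
  },
  "protected_blocks": [],
  "gap_blocks": {
    "E": [
      [200, 250]
    ]
  },
  "seed": 11,
  "width": 356
}
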