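{
  "group": 1,
  "case": 1,
  "sources": [1],
  "thresholds": {"p_s1": 0.7, "p_s2": 0.4},
  "status": "reference",
  "high": [1, 2],
  "medium": [4, 5, 6, 8, 9, 14, 15, 22, 25, 26, 27],
  "low": [3, 7, 10, 11, 12, 13, 16, 17, 18, 19, 20, 21, 23, 24, 28, 29, 30,
          31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46,
          47, 48, 49, 50]
}
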