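{
  "group": 1,
  "case": 2,
  "sources": [1, 22],
  "thresholds": {"p_s1": 0.7, "p_s2": 0.4},
  "status": "reference",
  "high": [1, 2, 8, 9, 22],
  "medium": [4, 5, 6, 14, 15, 25, 26, 27, 28, 49],
  "low": [3, 7, 10, 11, 12, 13, 16, 17, 18, 19, 20, 21, 23, 24, 29, 30, 31,
          32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47,
          48, 50]
}
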