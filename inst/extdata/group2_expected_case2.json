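{
  "group": 2,
  "case": 2,
  "sources": [1, 22],
  "thresholds": {"p_s1": 0.7, "p_s2": 0.4},
  "status": "informational",
  "note": "These published group-2 level lists are not reproducible under any consistent reading of the propagation rules validated on group 1; they are shipped for documentation only and are not asserted by the test suite.",
  "high": [1, 2, 9, 22, 23],
  "medium": [5, 8, 35, 37, 38, 39, 42, 49],
  "low": [3, 4, 6, 7, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 24,
          25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 36, 40, 41, 43, 44, 45,
          46, 47, 48, 50]
}
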