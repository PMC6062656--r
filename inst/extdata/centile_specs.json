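[
  {
    "variable": "hr",
    "resolution": 1,
    "lower": {
      "3": 0.01,
      "2": 0.05,
      "1": 0.1
    },
    "upper": {
      "1": 0.9,
      "2": 0.95,
      "3": 0.99
    }
  },
  {
    "variable": "rr",
    "resolution": 1,
    "lower": {
      "3": 0.01,
      "2": 0.05,
      "1": 0.1
    },
    "upper": {
      "1": 0.9,
      "2": 0.95,
      "3": 0.99
    }
  },
  {
    "variable": "sbp",
    "resolution": 1,
    "lower": {
      "3": 0.01,
      "2": 0.05,
      "1": 0.1
    },
    "upper": {
      "1": 0.9,
      "2": 0.95,
      "3": 0.99
    }
  },
  {
    "variable": "temp",
    "resolution": 0.1,
    "lower": {
      "3": 0.01,
      "1": 0.1
    },
    "upper": {
      "1": 0.9,
      "3": 0.99
    }
  },
  {
    "variable": "spo2",
    "resolution": 1,
    "lower": {
      "3": 0.02,
      "2": 0.1,
      "1": 0.2
    },
    "upper": {}
  }
]
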