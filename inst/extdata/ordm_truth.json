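{
  "model": "ordm",
  "natural": {
    "items": [
      {
        "intercepts": [-0.39000000000000001, -4.4779999999999998, -9.7989999999999995],
        "effects": {
          "a1": 3.7349999999999999
        }
      },
      {
        "intercepts": [-0.83399999999999996, -3.0150000000000001, -6.1419999999999995],
        "effects": {
          "a1": 1.9710000000000001
        }
      },
      {
        "intercepts": [-1.5329999999999999, -4.9100000000000001, -8.1039999999999992],
        "effects": {
          "a1": 2.8410000000000002
        }
      },
      {
        "intercepts": [0.28899999999999998, -1.8910000000000002, -5.6749999999999998],
        "effects": {
          "a1": 2.9020000000000001
        }
      },
      {
        "intercepts": [1.9910000000000001, 1.9620000000000002, 0.60999999999999999],
        "effects": {
          "a2": 2.29
        }
      },
      {
        "intercepts": [1.3520000000000001, 0.68200000000000005, -1.9039999999999999],
        "effects": {
          "a2": 2.6259999999999999
        }
      },
      {
        "intercepts": [0.070999999999999994, -1.2990000000000002, -3.5960000000000001],
        "effects": {
          "a2": 2.0390000000000001
        }
      },
      {
        "intercepts": [0.64600000000000002, -9.7489999999999988, -22.481999999999999],
        "effects": {
          "a2": 12.427
        }
      }
    ],
    "shared": null
  },
  "pseudo": {
    "items": [
      {
        "intercepts": [-0.39000000000000001, -4.0880000000000001, -5.3209999999999997],
        "effects": {
          "a1": 3.7349999999999999
        }
      },
      {
        "intercepts": [-0.83399999999999996, -2.181, -3.1269999999999993],
        "effects": {
          "a1": 1.9710000000000001
        }
      },
      {
        "intercepts": [-1.5329999999999999, -3.3770000000000002, -3.1939999999999991],
        "effects": {
          "a1": 2.8410000000000002
        }
      },
      {
        "intercepts": [0.28899999999999998, -2.1800000000000002, -3.7839999999999998],
        "effects": {
          "a1": 2.9020000000000001
        }
      },
      {
        "intercepts": [1.9910000000000001, -0.028999999999999915, -1.3520000000000003],
        "effects": {
          "a2": 2.29
        }
      },
      {
        "intercepts": [1.3520000000000001, -0.67000000000000004, -2.5859999999999999],
        "effects": {
          "a2": 2.6259999999999999
        }
      },
      {
        "intercepts": [0.070999999999999994, -1.3700000000000001, -2.2969999999999997],
        "effects": {
          "a2": 2.0390000000000001
        }
      },
      {
        "intercepts": [0.64600000000000002, -10.395, -12.733000000000001],
        "effects": {
          "a2": 12.427
        }
      }
    ],
    "shared": null
  }
}
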