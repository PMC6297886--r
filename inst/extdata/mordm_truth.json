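{
  "model": "mordm",
  "natural": {
    "items": [
      {
        "intercept": 5.8339999999999996,
        "effects": {
          "a1": 2.472
        }
      },
      {
        "intercept": 5.141,
        "effects": {
          "a1": 2.512
        }
      },
      {
        "intercept": 4.4909999999999997,
        "effects": {
          "a1": 2.7320000000000002
        }
      },
      {
        "intercept": 6.4240000000000004,
        "effects": {
          "a1": 3.2000000000000002
        }
      },
      {
        "intercept": 10.313000000000001,
        "effects": {
          "a2": 3.262
        }
      },
      {
        "intercept": 9.3390000000000004,
        "effects": {
          "a2": 2.3479999999999999
        }
      },
      {
        "intercept": 7.9480000000000004,
        "effects": {
          "a2": 1.6220000000000001
        }
      },
      {
        "intercept": 8.2850000000000001,
        "effects": {
          "a2": 2.0329999999999999
        }
      }
    ],
    "shared": [
      {
        "set": "{A1}",
        "intercepts": [-6.2039999999999997, -9.0749999999999993, -12.856]
      },
      {
        "set": "{A2}",
        "intercepts": [-7.8929999999999998, -8.4199999999999999, -10.531000000000001]
      }
    ]
  },
  "pseudo": {
    "items": [
      {
        "intercept": 5.8339999999999996,
        "effects": {
          "a1": 2.472
        }
      },
      {
        "intercept": 5.141,
        "effects": {
          "a1": 2.512
        }
      },
      {
        "intercept": 4.4909999999999997,
        "effects": {
          "a1": 2.7320000000000002
        }
      },
      {
        "intercept": 6.4240000000000004,
        "effects": {
          "a1": 3.2000000000000002
        }
      },
      {
        "intercept": 10.313000000000001,
        "effects": {
          "a2": 3.262
        }
      },
      {
        "intercept": 9.3390000000000004,
        "effects": {
          "a2": 2.3479999999999999
        }
      },
      {
        "intercept": 7.9480000000000004,
        "effects": {
          "a2": 1.6220000000000001
        }
      },
      {
        "intercept": 8.2850000000000001,
        "effects": {
          "a2": 2.0329999999999999
        }
      }
    ],
    "shared": [
      {
        "set": "{A1}",
        "intercepts": [-6.2039999999999997, -2.8709999999999996, -3.7810000000000006]
      },
      {
        "set": "{A2}",
        "intercepts": [-7.8929999999999998, -0.52700000000000014, -2.1110000000000007]
      }
    ]
  }
}
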