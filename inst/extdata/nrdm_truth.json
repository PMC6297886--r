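{
  "model": "nrdm",
  "natural": {
    "items": [
      {
        "intercepts": [-0.42299999999999999, -11.133000000000001, -23.710999999999999],
        "effects": {
          "a1": [3.6190000000000002, 13.958, 24.939]
        }
      },
      {
        "intercepts": [-0.93400000000000005, -3.1990000000000003, -5.1260000000000003],
        "effects": {
          "a1": [2.149, 4.1440000000000001, 4.8879999999999999]
        }
      },
      {
        "intercepts": [-1.5569999999999999, -8.4570000000000007, -19.274999999999999],
        "effects": {
          "a1": [2.714, 9.0679999999999996, 19.548999999999999]
        }
      },
      {
        "intercepts": [0.26900000000000002, -4.2709999999999999, -7.7620000000000005],
        "effects": {
          "a1": [3.8860000000000001, 9.2050000000000001, 11.712]
        }
      },
      {
        "intercepts": [1.986, 1.95, 0.70899999999999985],
        "effects": {
          "a2": [16.908000000000001, 19.664000000000001, 21.794]
        }
      },
      {
        "intercepts": [1.347, 0.63100000000000001, -1.6740000000000002],
        "effects": {
          "a2": [17.927, 20.707000000000001, 23.029]
        }
      },
      {
        "intercepts": [0.29599999999999999, -1.554, -3.8090000000000002],
        "effects": {
          "a2": [0.92600000000000005, 3.7830000000000004, 5.7229999999999999]
        }
      },
      {
        "intercepts": [0.64200000000000002, -9.6639999999999997, -20.701999999999998],
        "effects": {
          "a2": [18.138999999999999, 30.495999999999999, 41.211999999999996]
        }
      }
    ],
    "shared": null
  },
  "pseudo": {
    "items": [
      {
        "intercepts": [-0.42299999999999999, -10.710000000000001, -12.577999999999998],
        "effects": {
          "a1": [3.6190000000000002, 10.339, 10.981]
        }
      },
      {
        "intercepts": [-0.93400000000000005, -2.2650000000000001, -1.927],
        "effects": {
          "a1": [2.149, 1.9950000000000001, 0.74399999999999977]
        }
      },
      {
        "intercepts": [-1.5569999999999999, -6.9000000000000004, -10.817999999999998],
        "effects": {
          "a1": [2.714, 6.3539999999999992, 10.481]
        }
      },
      {
        "intercepts": [0.26900000000000002, -4.54, -3.4910000000000005],
        "effects": {
          "a1": [3.8860000000000001, 5.319, 2.5069999999999997]
        }
      },
      {
        "intercepts": [1.986, -0.036000000000000032, -1.2410000000000001],
        "effects": {
          "a2": [16.908000000000001, 2.7560000000000002, 2.129999999999999]
        }
      },
      {
        "intercepts": [1.347, -0.71599999999999997, -2.3050000000000002],
        "effects": {
          "a2": [17.927, 2.7800000000000011, 2.3219999999999992]
        }
      },
      {
        "intercepts": [0.29599999999999999, -1.8500000000000001, -2.2549999999999999],
        "effects": {
          "a2": [0.92600000000000005, 2.8570000000000002, 1.9399999999999995]
        }
      },
      {
        "intercepts": [0.64200000000000002, -10.305999999999999, -11.037999999999998],
        "effects": {
          "a2": [18.138999999999999, 12.356999999999999, 10.715999999999998]
        }
      }
    ],
    "shared": null
  }
}
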