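{
  "k1": 0.000416667,
  "k2": 0.004166667,
  "k3": 0.02,
  "k4": 1.67e-05,
  "k6": 0.01,
  "k7": 0.0025,
  "k8": 0.01,
  "k10": 0.01,
  "k11": 0.0008333,
  "k12": 0.01,
  "k13": 0.5,
  "k14": 0.005,
  "k15": 0.001667,
  "k16": 0.078,
  "k17": 0.001155,
  "k18": 1.155e-05,
  "k19": 0.000825,
  "k20": 0.0001,
  "k21": 0.0001,
  "k22": 0.000495,
  "k23": 0.000433,
  "k24": 1,
  "k25": 2e-05,
  "k26": 3.3e-05,
  "k27": 0.01,
  "k28": 0.001,
  "k29": 0.001,
  "k30": 0.001,
  "k31": 0.0001,
  "k32": 0.002,
  "k33": 0.005,
  "x1_0": 0.01,
  "x2_0": 0.01,
  "x3_0": 0.01,
  "x4_0": 0,
  "x5_0": 0,
  "x6_0": 0,
  "x7_0": 0,
  "x8_0": 0,
  "x9_0": 0,
  "x10_0": 0,
  "x11_0": 0,
  "x12_0": 0,
  "x13_0": 0,
  "ir_dose": 0,
  "typo_policy": {
    "mpf_activation_denominator_k6": true,
    "mpf_decay_michaelis": true,
    "arf_decay_linear": true,
    "p21_mpf_mass_action": true,
    "inactive_fractions_from_x2_x3": true,
    "k1_literal_exponent": false,
    "k14_policy": "calibrated"
  },
  "time_unit": "s"
}
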