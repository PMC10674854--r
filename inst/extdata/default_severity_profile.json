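{
  "_comment": "Default severity-graded simulation profile. Per class: rate/amplitude/slope1/slope2 are [mean, sd] (taps/s, palm units, palm units per tap); bp_frac, halt_depth, tremor_freq, tremor_amp are [min, max] uniform ranges; halts is an inclusive integer count range; noise_sd is a fraction of the base amplitude; duration in seconds.",
  "0": {
    "rate": [2.8, 0.25],
    "amplitude": [1.25, 0.1],
    "slope1": [0, 0.003],
    "slope2": [0, 0.002],
    "bp_frac": [0.7, 0.9],
    "halts": [0, 0],
    "halt_depth": [0.5, 0.9],
    "tremor_freq": [4, 6],
    "tremor_amp": [0, 0.02],
    "noise_sd": 0.02,
    "duration": 4
  },
  "1": {
    "rate": [2.3, 0.2],
    "amplitude": [1.1, 0.1],
    "slope1": [0, 0.004],
    "slope2": [-0.04, 0.008],
    "bp_frac": [0.7, 0.85],
    "halts": [0, 2],
    "halt_depth": [0.5, 0.85],
    "tremor_freq": [4, 6],
    "tremor_amp": [0, 0.03],
    "noise_sd": 0.03,
    "duration": 4.5
  },
  "2": {
    "rate": [1.8, 0.2],
    "amplitude": [0.95, 0.1],
    "slope1": [-0.005, 0.004],
    "slope2": [-0.06, 0.01],
    "bp_frac": [0.4, 0.6],
    "halts": [3, 5],
    "halt_depth": [0.5, 0.85],
    "tremor_freq": [4, 6],
    "tremor_amp": [0, 0.04],
    "noise_sd": 0.04,
    "duration": 5.5
  },
  "3": {
    "rate": [1.3, 0.15],
    "amplitude": [0.8, 0.1],
    "slope1": [-0.01, 0.005],
    "slope2": [-0.05, 0.01],
    "bp_frac": [0.1, 0.2],
    "halts": [6, 8],
    "halt_depth": [0.5, 0.85],
    "tremor_freq": [4, 6],
    "tremor_amp": [0.02, 0.06],
    "noise_sd": 0.05,
    "duration": 7.5
  },
  "4": {
    "rate": [0.8, 0.12],
    "amplitude": [0.3, 0.06],
    "slope1": [-0.01, 0.005],
    "slope2": [-0.015, 0.005],
    "bp_frac": [0.3, 0.5],
    "halts": [1, 2],
    "halt_depth": [0.5, 0.8],
    "tremor_freq": [4, 6],
    "tremor_amp": [0.02, 0.08],
    "noise_sd": 0.06,
    "duration": 6
  }
}
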