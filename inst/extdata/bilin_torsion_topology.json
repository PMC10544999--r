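{
  "CYC": {
    "tau1": ["NA", "C4A", "CHB", "C1B"],
    "tau2": ["C4A", "CHB", "C1B", "NB"],
    "tau3": ["NB", "C4B", "CHC", "C1C"],
    "tau4": ["C4B", "CHC", "C1C", "NC"],
    "tau5": ["NC", "C4C", "CHD", "C1D"],
    "tau6": ["C4C", "CHD", "C1D", "ND"]
  },
  "MBV": {
    "tau1": ["NA", "C4A", "CHB", "C1B"],
    "tau2": ["C4A", "CHB", "C1B", "NB"],
    "tau3": ["NB", "C4B", "CHC", "C1C"],
    "tau4": ["C4B", "CHC", "C1C", "NC"],
    "tau5": ["NC", "C4C", "CHD", "C1D"],
    "tau6": ["C4C", "CHD", "C1D", "ND"]
  },
  "DBV": {
    "tau1": ["NA", "C4A", "CHB", "C1B"],
    "tau2": ["C4A", "CHB", "C1B", "NB"],
    "tau3": ["NB", "C4B", "CHC", "C1C"],
    "tau4": ["C4B", "CHC", "C1C", "NC"]
  }
}
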