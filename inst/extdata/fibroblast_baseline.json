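{
  "model": "active atrial fibroblast, MacCannell/Maleckar four-current formulation",
  "version": "0.1.0",
  "units": {
    "conductance": "nS",
    "current": "pA",
    "capacitance": "pF",
    "concentration": "mM",
    "time": "ms",
    "voltage": "mV"
  },
  "parameters": {
    "Cm": 6.3,
    "g_Kv": 1.575,
    "g_K1": 3.04,
    "I_NaK_max": 12.6,
    "g_bNa": 0.1416586,
    "k_NaK_K": 1.0,
    "k_NaK_Na": 11.0,
    "Na_i": 8.5547,
    "K_i": 129.43,
    "Na_o": 130.0,
    "K_o": 5.4
  },
  "initial": {
    "V": -47.75
  }
}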