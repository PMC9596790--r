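{
  "model": "human atrial myocyte, Nygren-family formulation with AF-type remodelling and SK current",
  "version": "0.1.0",
  "units": {
    "conductance": "nS",
    "current": "pA",
    "capacitance": "pF",
    "concentration": "mM",
    "volume": "L",
    "time": "ms",
    "voltage": "mV",
    "D": "cm^2/ms"
  },
  "parameters": {
    "Cm": 66.0,
    "g_Na": 740.0,
    "g_CaL": 22.0,
    "g_t": 7.5,
    "g_Kur": 1.6,
    "g_Ks": 1.3,
    "g_Kr": 1.8,
    "g_K1": 5.0,
    "g_SK": 0.8,
    "I_NaK_max": 110.0,
    "k_NaK_K": 1.0,
    "k_NaK_Na": 11.0,
    "k_NaCa": 0.02,
    "gamma_NaCa": 0.45,
    "d_NaCa": 0.0003,
    "I_CaP_max": 2.0,
    "k_CaP": 0.0002,
    "g_bNa": 0.1516221,
    "g_bCa": 0.0625,
    "Na_o": 130.0,
    "K_o": 5.4,
    "Ca_o": 1.8,
    "E_CaL_app": 60.0,
    "k_Ca_inact": 0.00035,
    "EC50_SK": 0.0007,
    "Vol_i": 5.884e-12,
    "Vol_sr": 4.4e-13,
    "buf_i": 0.05,
    "buf_sr": 0.15,
    "V_max_up": 0.003,
    "K_up": 0.0006,
    "g_rel": 0.005,
    "K_rel_inact": 0.0006,
    "tau_rel_act": 3.0,
    "tau_rel_inact": 60.0,
    "D": 0.00125,
    "k_SR_leak": 6e-05
  },
  "initial": {
    "V": -79.83,
    "Nai": 8.5547,
    "Ki": 129.43,
    "Cai": 6.5e-05,
    "CaSR": 0.6
  }
}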