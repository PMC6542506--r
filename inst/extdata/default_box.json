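{
  "h_e_rest": [-80, -60],
  "h_i_rest": [-80, -60],
  "h_e_eq": [-20, 10],
  "h_i_eq": [-90, -60],
  "S_e_max": [0.05, 0.5],
  "S_i_max": [0.05, 0.5],
  "mu_e": [-55, -40],
  "mu_i": [-55, -40],
  "sigma_e": [2, 7],
  "sigma_i": [2, 7],
  "tau_e": [5, 150],
  "tau_i": [5, 150],
  "gamma_e": [0.1, 1],
  "gamma_i": [0.01, 0.5],
  "Gamma_e": [0.1, 2],
  "Gamma_i": [0.1, 2],
  "p_ee": [0, 10],
  "p_ei": [0, 10],
  "N_ee": [2000, 5000],
  "N_ie": [100, 1000],
  "N_ei": [2000, 5000],
  "N_ii": [100, 1000],
  "p_ie": [0],
  "p_ii": [0]
}
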