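{
  "name": "nn-ei-default",
  "comment": "Excitatory/inhibitory neural-network defaults (1:1 ratio). Deactivation alpha = 0.1 per ms is the standard relaxation rate of stochastic spiking-population models; the response function is tanh clipped at zero. The coupling is balanced (inhibition partially cancels excitation) with net recurrent gain w_E - w_I = 0.3, which places the critical network size inside the unit sweep range; the external drive h and the activation leak are small so that quiescent firing is sparse on the 4-ms avalanche-binning scale.",
  "time_unit": "ms",
  "N0": 200,
  "omega": 1,
  "ei_ratio": [1, 1],
  "w_E": 0.5,
  "w_I": 0.2,
  "h": 1e-4,
  "alpha": 0.1,
  "leak": 1e-4,
  "response": "tanh_plus"
}
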