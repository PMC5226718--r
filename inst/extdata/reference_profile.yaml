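# Reference parameter profile of the five-population attractor network.
# All values are the package defaults; an empty profile is equivalent.
# Units: nF, nS, mV, ms, Hz, mM.
network:
  "N": 1000
  f: 0.2
  w_plus: 1.500
  w_minus: 0.878
  N_ext: 800
  nu_ext_source: 3        # background 3 Hz per source = 2.4 kHz total
neuron:
  Cm_exc: 0.5
  Cm_inh: 0.2
  g_L_exc: 25             # membrane time constants 20 ms / 10 ms
  g_L_inh: 20
  V_L: -70
  V_thr: -50
  V_reset: -55
  tau_rp_exc: 2
  tau_rp_inh: 1
synapse:
  g_ampa_ext_exc: 2.08
  g_ampa_ext_inh: 1.62
  g_ampa_rec_exc: 0.104
  g_ampa_rec_inh: 0.081
  g_nmda_exc: 0.327
  g_nmda_inh: 0.258
  g_gaba_exc: 1.287
  g_gaba_inh: 1.002
  tau_ampa: 2
  tau_gaba: 10
  tau_nmda_rise: 2
  tau_nmda_decay: 100
  alpha: 0.5
  V_E: 0
  V_I: -70
  mg: 1
decision:
  theta: 28               # multistable operating point (lambda = 50 Hz)
  sustain: 50
  window: 50
  step: 5
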