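# Example photoalloc configuration. Every section is optional; omitted
# entries fall back to package defaults. Units: I umol quanta m-2 s-1,
# T_leaf degrees C, CO2 ubar, O2 mbar, N_t mmol m-2, energies J mol-1.
constants:
  Theta: 0.7
  h_per_atp: 4
species:
  my_c4:
    ptype: C4
    beta: 0.95
    k_ccat: 5.44
    xi: 1
    K_p: 80
    g_s: 0.003
    allocation_bounds:
      n_Etot: [0.0, 1.0]
      n_C4: [0.0, 1.0]
environments:
  my_growth_chamber:
    I: 600
    T_leaf: 28
    N_t: 110
    C_a: 400
    O: 210
temperature:
  V_pmax: {E: 94800, H: 73300, S: 250}
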