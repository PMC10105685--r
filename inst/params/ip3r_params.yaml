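# Fitted ligand-dependence parameter registry for IP3R1 wild-type and
# D2594K/D2594A mutant channels. Concentrations in mol/L, potentials in mV,
# times in s. Po ceilings (pmax) and the feedthrough `range` are not fitted
# quantities here but documented defaults (mutant Po ceiling 3.6x WT for the
# IP3 axis, ~3x for the cytosolic Ca2+ axis); EC50/IC50 recovery analyses are
# invariant to these scalings.

wt_atp:
  model: hill
  pmax: 2.0          # dF/F0 ceiling (plate assay)
  ec50: 1.09e-05
  h: 1.5
d2594k_atp:
  model: hill
  pmax: 4.0
  ec50: 3.3e-06
  h: 1.5

wt_ip3:
  model: hill
  pmax: 0.1
  ec50: 6.6e-07
  h: 1.8
d2594k_ip3:
  model: hill
  pmax: 0.36
  ec50: 4.06e-07
  h: 2.0

wt_cyto_ca:
  model: biphasic
  pmax: 0.1
  ec50_act: 7.8e-08
  h_act: 2.0
  ic50_inh: 5.62e-07
  h_inh: 2.0
d2594k_cyto_ca:
  model: biphasic
  pmax: 0.3
  ec50_act: 1.01e-07
  h_act: 2.0
  ic50_inh: 1.38e-06
  h_inh: 2.0
d2594a_cyto_ca:
  model: biphasic
  pmax: 0.1
  ec50_act: 8.9e-08
  h_act: 2.0
  ic50_inh: 3.99e-07
  h_inh: 2.0

wt_mot_edf:
  model: mot_edf
  range: 2.5
  va50: 111.5
  ha: 7.8
  vi50: 170.7
  hi: 3.7

wt_puffs:
  model: puffs
  fdhm: 0.68
  rate: 0.04
d2594k_puffs:
  model: puffs
  fdhm: 2.39
  rate: 0.1
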