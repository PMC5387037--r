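# Reference simulation scenario: C3 leaf under ambient O2.
# Units: fluxes umol m-2 s-1; KmC ubar; KmO, O mbar; Sco mbar/ubar;
# gm_dif mol m-2 s-1 bar-1; ci_grid ubar.
photo:
  Vcmax: 80
  J: 125
  Rd: 1
  KmC: 291
  KmO: 194
  Sco: 3.1
  O: 210
resistance:
  gm_dif: 0.4
  omega: 0.5
  sigma: 0.5
ci_grid: {start: 50, stop: 500, step: 10}
o2_levels: [20, 210, 400]
noise_sd: 0.2
seed: 42
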