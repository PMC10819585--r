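name: default
note: Six screening values shipped for seven metals; aligned to Ni, Cu, Zn, As, Cd,
  Pb. Cr = 250 mg/kg back-calculated from mean concentration / mean risk index (2*54.62/0.437)
  and equal to the national farmland screening value at pH > 7.5.
screening:
  Cr: 250.0
  Ni: 190.0
  Cu: 100.0
  Zn: 300.0
  As: 25.0
  Cd: 0.6
  Pb: 170.0
background:
  Cr: 64.75
  Ni: 30.23
  Cu: 22.43
  Zn: 62.659999999999997
  As: 11.52
  Cd: 0.0763
  Pb: 20.16
toxicity:
  Cr: 2.0
  Ni: 5.0
  Cu: 5.0
  Zn: 1.0
  As: 10.0
  Cd: 30.0
  Pb: 5.0
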