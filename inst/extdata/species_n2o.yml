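# Default species system of an acetate-fed N2O-respiring enrichment.
# Formulas accept fractional subscripts and trailing charge tokens.
species:
  - name: acetate
    formula: C2H3O2-
    measured: true
    role: electron_donor
  - name: n2o
    formula: N2O
    measured: true
    role: electron_acceptor
    phase: gas
  - name: nh4
    formula: NH4+
    measured: true
    role: n_source
  - name: biomass
    formula: CH1.8O0.5N0.2
    measured: true
    role: biomass
    phase: solid
  - name: co2
    formula: CO2
    phase: gas
  - name: n2
    formula: N2
    phase: gas
  - name: h2o
    formula: H2O
  - name: h
    formula: H+
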