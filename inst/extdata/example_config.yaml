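# Example dualosc model configuration: lac-reporter circuit with both
# competition channels enabled and two parameter overrides. Any field of
# circuitConfig() / oscillatorParameters() may appear; unknown keys are
# rejected. Units: molecules/cell and minutes (inducers: % w/v, mM).
circuit:
  reporter_kind: lac
  retroactivity_on: true
  protease_sharing_on: true
  n_activator_dna: 50
  n_repressor_dna: 25
parameters:
  V_max: 420
  tx_rep_lac: 0.24
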