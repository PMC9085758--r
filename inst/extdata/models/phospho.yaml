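# Allosteric PKA phosphorylation model (well-mixed): stimulating influx.
# Placeholder-provenance rate constants live in phospho_params(); only the
# run-level settings are configured here.
model: phospho
duration: {value: 300, unit: s}
params:
  influx: {value: 200, unit: nM/s}
  camp_binding: {value: 0.07, unit: uM^-1 s^-1}
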