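# cAMP compartmentalisation: storage region with reduced permeability,
# membrane ring with two passages, high hydrolysis.
model: compartment
duration: {value: 300, unit: s}
params:
  permeability: 0.01
  passages: 2
  hydrolysis: {value: 2, unit: "1/s", provenance: placeholder}
  influx: {value: 200, unit: nM/s}
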