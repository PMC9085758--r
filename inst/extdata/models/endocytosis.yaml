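# Clathrin-mediated endocytosis on a 1 um^2 apical membrane patch.
model: endocytosis
duration: {value: 300, unit: s}
seed: 1
params:
  influx: {value: 100, unit: nM/s}
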