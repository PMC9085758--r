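# Full AQP2 recycling model, scaled-down activation variant. The cAMP
# influx schedule (400/200/50 nM/s) is built into the model defaults.
model: full
duration: {value: 120, unit: s}
seed: 1
params:
  variant: activation
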