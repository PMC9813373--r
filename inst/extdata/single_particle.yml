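# Single-swimmer run at the default experimental parameters, programmed
# delay in the bimodal regime.  Load with load_config().
v0: 2.16
delta_t: 1.14
duration: 620
dt: 0.002
seed: 1
sample_every: 5
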