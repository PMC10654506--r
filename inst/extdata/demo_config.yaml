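# Demo configuration for the generative retinocollicular model.
# Any subset of the sim_config() fields may be set; the rest keep their
# defaults (see ?sim_config).
sigma: 27          # axonal projection jitter SD, um
lambda_mean: 5.5   # mean RGC inputs per SC neuron
grid_rows: 9
grid_cols: 9
seed: 1
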