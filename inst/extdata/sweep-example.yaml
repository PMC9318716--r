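# Example ratio-sweep configuration (see ?read_sweep_config).
# `values` is the tuning parameter of the chosen system:
#   arfima -> 1 - rho (white noise at 1, long memory towards 0)
#   lorenz -> eta (observational-noise amplitude)
system: arfima
values: [0.1, 0.3, 0.5, 0.7, 0.9]
m: [4, 5]
l: 100
seed: 1
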