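# local reproduction with 1/100 global matings
landscape_name: fig1_default
lattice_size: 70
mu: 0.002
r: 0.1
reproduction: local
rare_global_prob: 0.01
max_epochs: 2000
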