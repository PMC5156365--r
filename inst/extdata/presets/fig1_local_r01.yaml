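# one run of the main factorial's local, r = 0.1 cell
landscape_name: fig1_default
lattice_size: 70
mu: 0.002
r: 0.1
reproduction: local
max_epochs: 2000
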