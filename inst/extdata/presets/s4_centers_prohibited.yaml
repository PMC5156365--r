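# valley-crossing with the centers-prohibited mate replacement
landscape_name: s4_valley
lattice_size: 70
mu: 0.001
r: 0.5
reproduction: local
init_genotype: "00"
init_density: 0.8
centers_genotype: "11"
centers_threshold: 0.01
max_epochs: 2000
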