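# suture counting: lethal double mutant, local reproduction
landscape_name: s3_lethal
lattice_size: 70
mu: 1.0e-5
r: 0.5
reproduction: local
init_genotype: "00"
stop_genotype: none
max_epochs: 3000
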