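subgenome	n_pseudomolecules	length_mb	n_on_array	n_polymorphic
A	10	1070	29983	23559
B	10	1360	28250	20865
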