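stage	count
input	163782
identical	11
both_genomes	46205
both_strands	50642
ambiguous_multiallelic	825
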