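species	n_on_array	n_polymorphic
A. hypogaea	44501	34183
A. cardenasii	2195	1643
A. duranensis	3834	2912
A. stenosperma	2389	2096
A. magna	2605	1367
A. batizocoi	2709	2223
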