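sample_id	variant_label	dna_alt	dna_ref	rna_alt	rna_ref
sample1	p.Glu79*	46	54	9	91
sample2	p.Lys137Aspfs*26	56	44	32	68
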