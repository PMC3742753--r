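fusion_id	gene_a	variant_a	n_exons_a	gene_b	variant_b	n_exons_b
TOY1	GENEA	v1	5	GENEB	v1	4
TOY2	GENEA	v1	5	GENEC	v1	6
TOY3	GENED	v1	13	GENEE	v1	10
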