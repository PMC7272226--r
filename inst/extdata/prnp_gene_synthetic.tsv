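gene_id	symbol	expected_lof	pli	coding_codons
PRNP_SYN	PRNP_SYN	10.65	0.0	253
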