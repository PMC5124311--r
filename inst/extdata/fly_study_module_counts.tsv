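quantity	n_genes
analyzed_transcriptome	16292
assigned_to_modules	7744
dc_total	2994
dc_within_modules	1169
dc_between_module_pairs	1011
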