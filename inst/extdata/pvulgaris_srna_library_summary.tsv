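n_libraries	total_raw_reads	total_mappable_reads	pct_mappable_24nt	pct_mappable_21nt
12	230953396	175032524	29.90	13.5
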