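marker	chrom	pos_bp	coded	other
mk_at	11	1e+06	A	T
mk_rare	11	2e+06	A	G
mk_hwe	11	3e+06	A	G
mk_ok1	11	4e+06	A	G
mk_ok2	11	5e+06	A	G
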