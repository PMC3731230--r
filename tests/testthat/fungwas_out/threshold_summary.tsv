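p_thresh	observed_count	expected_count	fdr	fdr_percent	tp_fraction	tp_percent
5.6e-06	0	0	NA	undefined	NA	undefined
0.015	7	2.76	0.394285714285714	39%	0.605714285714286	61%
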