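exposure	outcome	or	ci_low	ci_high	pvalue
telomere_length	lymphoid_leukaemia	2.4249	1.4933	3.9377	0.0003
telomere_length	acute_lymphocytic_leukaemia	2.8931	1.2466	6.7145	0.0134
hannum_accel	chronic_myeloid_leukaemia	0.5553	0.3182	0.9690	0.0384
phenoage_accel	myeloid_leukaemia	1.3018	1.0596	1.5994	0.0120
phenoage_accel	chronic_lymphocytic_leukaemia	1.2280	1.0118	1.4905	0.0376
phenoage_accel	lymphoid_leukaemia	1.1539	1.0267	1.2968	0.0163
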