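rsid	locus	gene_product	mechanism	f_stat	variance_explained_pct
rs10741657	CYP2R1	cytochrome P450 2R1	hepatic 25-hydroxylation	18.78	0.13
rs12785878	DHCR7	7-dehydrocholesterol reductase	cutaneous synthesis	18.29	0.12
rs2282679	GC	vitamin D binding protein	transport	13.38	0.09
rs6013897	CYP24A1	cytochrome P450 24A1	catabolism	3.13	0.02
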