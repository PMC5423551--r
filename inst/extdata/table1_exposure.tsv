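rsid	effect_allele	other_allele	eaf	beta	se	p
rs10741657	C	T	0.62	-0.052	0.011999	3.3e-20
rs12785878	G	A	0.27	-0.056	0.013094	2.1e-27
rs2282679	C	T	0.3	-0.047	0.012849	1.9e-109
rs6013897	A	G	0.19	-0.027	0.015261	6.0e-10
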