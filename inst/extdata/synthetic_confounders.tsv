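rsid	confounder	p
rs10741657	BMI	0.29
rs12785878	BMI	0.41
rs2282679	BMI	0.55
rs6013897	BMI	0.73
rs10741657	smoking	0.18
rs12785878	smoking	0.34
rs2282679	smoking	0.62
rs6013897	smoking	0.88
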