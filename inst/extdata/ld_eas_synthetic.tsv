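rsid	rs12614	rs422951	rs378352	rs1883832	rs3130542	rs652888	rs2856718	rs7453920	rs3077	rs9277535	rs2853953	rs1419881
rs12614	1	0.8	0.8	0	0.8	0.8	0.8	0	0.8	0.8	0.8	0
rs422951	0.8	1	0.8	0	0.8	0.8	0.8	0	0.8	0.8	0.8	0
rs378352	0.8	0.8	1	0	0.8	0.8	0.8	0	0.8	0.8	0.8	0
rs1883832	0	0	0	1	0	0	0	0	0	0	0	0
rs3130542	0.8	0.8	0.8	0	1	0.8	0.8	0	0.8	0.8	0.8	0
rs652888	0.8	0.8	0.8	0	0.8	1	0.8	0	0.8	0.8	0.8	0
rs2856718	0.8	0.8	0.8	0	0.8	0.8	1	0	0.8	0.8	0.8	0
rs7453920	0	0	0	0	0	0	0	1	0	0	0	0
rs3077	0.8	0.8	0.8	0	0.8	0.8	0.8	0	1	0.8	0.8	0
rs9277535	0.8	0.8	0.8	0	0.8	0.8	0.8	0	0.8	1	0.8	0
rs2853953	0.8	0.8	0.8	0	0.8	0.8	0.8	0	0.8	0.8	1	0
rs1419881	0	0	0	0	0	0	0	0	0	0	0	1
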