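complex	term	mean	sem
glcnac12_unit2	inter_vdw	-92.36	1.20
glcnac12_unit2	inter_coulomb	-23.33	0.56
glcnac12_unit2	reaction_field	39.14	0.53
glcnac12_unit2	cavity	-14.81	0.19
glcnac12_unit3	inter_vdw	-90.26	0.67
glcnac12_unit3	inter_coulomb	-36.72	0.87
glcnac12_unit3	reaction_field	58.26	0.69
glcnac12_unit3	cavity	-15.98	0.73
glcnac3_unit2	inter_vdw	-66.44	0.82
glcnac3_unit2	inter_coulomb	-23.91	0.53
glcnac3_unit2	reaction_field	33.64	0.38
glcnac3_unit2	cavity	-11.09	0.06
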