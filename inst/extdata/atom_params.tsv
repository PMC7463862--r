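# Minimal per-atom parameter set for toy pocket / pseudo-GlcNAc systems.
# Pair rows: resname+atom set. Fallback rows: element only.
# Units: charge e, lj_epsilon kcal/mol, lj_rmin_half A, boundary_radius A.
resname	atom	element	charge	lj_epsilon	lj_rmin_half	boundary_radius
ASP	OD1	O	-0.80	0.2100	1.6612	1.6612
ASP	OD2	O	-0.80	0.2100	1.6612	1.6612
ASP	CG	C	0.60	0.0860	1.9080	1.9080
NAG	C1	C	0.75	0.1094	1.9080	1.9080
NAG	N2	N	-0.20	0.1700	1.8240	1.8240
NAG	O7	O	-0.55	0.2100	1.6612	1.6612
NAG	O3	O	-0.20	0.2104	1.7210	1.7210
WAT	OW	O	-0.834	0.1520	1.7683	1.7683
WAT	HW	H	0.417	0.0000	0.6000	0.6000
		C	0.00	0.1094	1.9080	1.9080
		N	-0.40	0.1700	1.8240	1.8240
		O	-0.40	0.2100	1.6612	1.6612
		H	0.20	0.0157	0.6000	0.6000
		S	0.00	0.2500	2.0000	2.0000
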