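# Wine-like spin-system fixture (synthetic).
# Only the two calibration anchors are authoritative by construction:
#   TSP 0.00 ppm and tartrate 4.47 ppm.
# All other chemical shifts, couplings, concentrations and T2 values are
# illustrative literature-style choices for a generic dry white wine and are
# NOT measured values.  Concentrations are relative amplitude units chosen so
# that solvents exceed metabolites by >= 3 orders of magnitude.
system	site	shift_ppm	n_protons	J_partner	J_hz	concentration	class	T2_s
water	H2O	4.80	2			100000	solvent	0.8
ethanol	CH3	1.18	3	CH2	7.1	10000	solvent	0.6
ethanol	CH2	3.65	2			10000	solvent	0.6
TSP	TMS	0.00	9			5	reference	0.5
tartrate	CH	4.47	2			20	metabolite	0.4
lactate	CH3	1.33	3	CH	6.9	10	metabolite	0.4
lactate	CH	4.11	1			10	metabolite	0.4
acetate	CH3	2.07	3			8	metabolite	0.5
succinate	CH2	2.61	4			5	metabolite	0.4
glycerol	CH2	3.56	4	CH	6.0	25	metabolite	0.35
glycerol	CH	3.78	1			25	metabolite	0.35
isopentanol	CH3	0.90	6	CH2	6.8	3	metabolite	0.4
isopentanol	CH2	1.46	2			3	metabolite	0.4
isobutanol	CH3	0.89	6	CH	6.7	2	metabolite	0.4
isobutanol	CH	1.75	1			2	metabolite	0.4
acetoin	CH3	1.37	3	CH	7.1	1.5	metabolite	0.4
acetoin	CH	4.41	1			1.5	metabolite	0.4
propanediol	CH2	1.80	2	CH2O	6.3	1.5	metabolite	0.4
propanediol	CH2O	3.68	4			1.5	metabolite	0.4
myoinositol	H5	3.27	1	H46	9.3	1.2	metabolite	0.35
myoinositol	H46	3.54	2			1.2	metabolite	0.35
alanine	CH3	1.48	3	CH	7.2	1	metabolite	0.4
alanine	CH	3.78	1			1	metabolite	0.4
proline	CH2g	2.00	2	CH2d	6.8	2	metabolite	0.35
proline	CH2d	3.35	2			2	metabolite	0.35
malate	CH	4.30	1	CH2	6.6	8	metabolite	0.4
malate	CH2	2.68	2			8	metabolite	0.4
citrate	CH2	2.75	4			3	metabolite	0.4
methanol	CH3	3.34	3			1.5	metabolite	0.5
galacturonate	H1	5.28	1	H2	7.8	1.2	metabolite	0.35
galacturonate	H2	3.51	1			1.2	metabolite	0.35
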