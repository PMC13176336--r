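lab_id	context	material	completeness_pct	mean_coverage	sex	endogenous_pct	enrichment_factor
HOLF001.A	Layer I, Magdalenian*	Dentin	96.46	19.53	M	0.135	1165.1
HOLF002.A	Layer I, Magdalenian	Dentin	43.08	2.50	-	0.017	451.5
HOLF003.A	Layer Vab, Aurignacian	Dentin	97.70	28.09	-	0.042	627.3
HOLF004.A	Layer IIa, Magdalenian*	Dentin	96.94	18.63	-	0.032	632.4
HOLF005.A	Layer IIb, Gravettian	Dentin	3.24	0.56	-	0.012	undefined
HOLF006.A	Layer IIb, Gravettian	Dentin	90.98	9.64	-	0.023	560.2
HOLF007.A	Layer IIc, Gravettian	Dentin	95.60	11.82	F	0.138	43.8
HOLF008.A	Layer IIc, Gravettian	Dentin	3.16	0.52	-	0.005	undefined
HOLF009.A	Layer IIcf, Gravettian	Dentin	98.17	33.64	M	0.185	665.0
HOLF010.A	Layer IIcf, Gravettian	Dentin	0.00	0.00	-	0.008	undefined
HOLF010.B	Layer IIcf, Gravettian	Cementum	98.16	36.29	F	1.455	452.6
HOLF011.A	Layer IIdb, Aurignacian	Dentin	0.00	0.08	-	0.007	28.8
HOLF012.A	Layer IId, Aurignacian	Dentin	90.90	9.00	F	0.095	771.4
HOLF013.A	Layer IIIa, Aurignacian	Dentin	6.34	0.81	-	0.016	65.0
HOLF014.A	Layer IIIa, Aurignacian	Dentin	0.21	0.26	-	0.006	undefined
HOLF015.A	Layer IIIb, Aurignacian	Dentin	0.56	0.19	-	0.013	undefined
HOLF016.A	Layer IIIb, Aurignacian	Dentin	77.12	6.42	-	0.055	70.9
HOLF017.A	Layer IV, Aurignacian	Dentin	28.88	1.87	-	0.059	undefined
HOLF018.A	Layer IV, Aurignacian	Dentin	0.09	0.14	-	0.009	59.3
HOLF019.A	Layer Va, Aurignacian	Dentin	0.00	0.07	-	0.007	undefined
HOLF020.A	Layer Va, Aurignacian	Dentin	2.75	0.57	-	0.015	undefined
HOLF021.A	Layer Vb, Aurignacian	Dentin	95.18	13.70	-	0.042	997.3
HOLF022.A	Layer Vb, Aurignacian	Dentin	98.92	123.06	M	20.199	250.8
HOLF023.A	Layer IIc, Gravettian	Dentin	64.31	3.83	-	0.02	undefined
HOLF023.B	Layer IIc, Gravettian	Cementum	14.31	1.14	-	0.023	undefined
HOLF024.A	Layer IV, Aurignacian	Dentin	16.42	1.20	-	0.012	506.5
HOLF024.B	Layer IV, Aurignacian	Cementum	96.25	28.08	F	1.561	317.5
HOLF025.A	Layer Vaa, Aurignacian	Dentin	22.45	1.56	-	0.008	526.0
HOLF025.B	Layer Vaa, Aurignacian	Cementum	96.33	16.19	F	0.155	280.3
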