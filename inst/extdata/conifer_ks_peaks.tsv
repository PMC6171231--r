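taxonA	taxonB	nPairs	peak
P_kesiya	P_tabuliformis	6351	0.01
P_kesiya	P_sylvestris	4331	0.01
P_tabuliformis	P_sylvestris	898	0.01
P_kesiya	P_pinea	8112	0.03
P_tabuliformis	P_pinea	4144	0.03
P_sylvestris	P_pinea	1153	0.02
P_kesiya	P_halepensis	16051	0.03
P_tabuliformis	P_halepensis	5498	0.03
P_sylvestris	P_halepensis	727	0.02
P_pinea	P_halepensis	5839	0.03
P_kesiya	P_pinaster	7561	0.02
P_tabuliformis	P_pinaster	3311	0.03
P_sylvestris	P_pinaster	944	0.02
P_pinea	P_pinaster	3844	0.03
P_halepensis	P_pinaster	6419	0.03
P_kesiya	P_contorta	8922	0.03
P_tabuliformis	P_contorta	3953	0.03
P_sylvestris	P_contorta	1129	0.03
P_pinea	P_contorta	4392	0.04
P_halepensis	P_contorta	6578	0.04
P_pinaster	P_contorta	4011	0.03
P_kesiya	P_banksiana	7784	0.03
P_tabuliformis	P_banksiana	3577	0.03
P_sylvestris	P_banksiana	1374	0.03
P_pinea	P_banksiana	3815	0.04
P_halepensis	P_banksiana	5642	0.04
P_pinaster	P_banksiana	3610	0.04
P_contorta	P_banksiana	4996	0.01
P_kesiya	P_taeda	13493	0.04
P_tabuliformis	P_taeda	4981	0.03
P_sylvestris	P_taeda	2624	0.03
P_pinea	P_taeda	6114	0.04
P_halepensis	P_taeda	14088	0.04
P_pinaster	P_taeda	6496	0.04
P_contorta	P_taeda	6836	0.01
P_banksiana	P_taeda	5744	0.01
P_kesiya	P_palustris	9311	0.03
P_tabuliformis	P_palustris	3514	0.03
P_sylvestris	P_palustris	1092	0.03
P_pinea	P_palustris	4097	0.04
P_halepensis	P_palustris	8425	0.04
P_pinaster	P_palustris	4035	0.04
P_contorta	P_palustris	4321	0.01
P_banksiana	P_palustris	3994	0.01
P_taeda	P_palustris	7551	0.01
P_kesiya	P_monticola	7472	0.08
P_tabuliformis	P_monticola	3538	0.08
P_sylvestris	P_monticola	1433	0.06
P_pinea	P_monticola	4481	0.08
P_halepensis	P_monticola	5940	0.08
P_pinaster	P_monticola	3790	0.09
P_contorta	P_monticola	4773	0.07
P_banksiana	P_monticola	4769	0.06
P_taeda	P_monticola	4847	0.09
P_palustris	P_monticola	5087	0.08
P_kesiya	P_lambertiana	11185	0.08
P_tabuliformis	P_lambertiana	4477	0.08
P_sylvestris	P_lambertiana	1964	0.06
P_pinea	P_lambertiana	5233	0.08
P_halepensis	P_lambertiana	8269	0.09
P_pinaster	P_lambertiana	4783	0.08
P_contorta	P_lambertiana	5308	0.08
P_banksiana	P_lambertiana	4722	0.08
P_taeda	P_lambertiana	8349	0.08
P_palustris	P_lambertiana	6428	0.08
P_monticola	P_lambertiana	7169	0.01
P_kesiya	Picea_glauca	13691	0.14
P_tabuliformis	Picea_glauca	4808	0.15
P_sylvestris	Picea_glauca	959	0.14
P_pinea	Picea_glauca	6493	0.15
P_halepensis	Picea_glauca	12041	0.15
P_pinaster	Picea_glauca	5082	0.15
P_contorta	Picea_glauca	7999	0.14
P_banksiana	Picea_glauca	7092	0.14
P_taeda	Picea_glauca	9724	0.15
P_palustris	Picea_glauca	6019	0.14
P_monticola	Picea_glauca	7710	0.15
P_lambertiana	Picea_glauca	9969	0.15
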