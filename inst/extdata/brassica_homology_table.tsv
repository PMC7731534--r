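ref	B01_bp	B01_pct	B02_bp	B02_pct	B03_bp	B03_pct	B04_bp	B04_pct	B05_bp	B05_pct	B06_bp	B06_pct	B07_bp	B07_pct	B08_bp	B08_pct
A01	15185553	51.3			13228780	44.7										
A02			16418817	52.2									14535932	46.2		
A03					15196210	39.9	14502023	38	1218940	3.2	4307164	11.3				
A04							14898239	67.9	5900409	26.9					702255	3.2
A05	10591962	37.2							13872273	48.7	3293639	11.5				
A06			7524595	19.1	5158622	17.6			7315564	24.3	8704851	29.8				
A07	2818377	9.7					7270483	25.23					15688850	54.5		
A08													11410503	49.7	11463772	49.9
A09			21384087	47.3	10792098	23.9	126317	0.27	2342318	5.18	1203054	2.7	3813925	8.4		
A10	2004504	9.7	2508933	12.1	14954862	72.1									887503	4.2
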