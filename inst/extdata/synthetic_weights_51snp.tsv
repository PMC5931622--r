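rsid	effect_allele	other_allele	beta	in_grs12	in_grs51	haplotype_member	imputation_r2
rs7702675	A	G	0.133	TRUE	TRUE	FALSE	
rs7702724	C	T	0.084	TRUE	TRUE	FALSE	
rs7703683	A	C	0.178	TRUE	TRUE	FALSE	
rs7708729	T	C	0.064	TRUE	TRUE	FALSE	0.989
rs7709488	G	T	0.073	TRUE	TRUE	FALSE	
rs7712483	A	G	0.083	TRUE	TRUE	FALSE	
rs7713702	G	A	0.142	TRUE	TRUE	FALSE	0.972
rs7716895	G	T	0.115	TRUE	TRUE	FALSE	0.962
rs7717678	A	G	0.179	FALSE	TRUE	FALSE	
rs7718363	C	T	0.045	FALSE	TRUE	FALSE	
rs7719035	A	C	0.178	FALSE	TRUE	FALSE	
rs7722880	A	C	0.109	FALSE	TRUE	FALSE	0.92
rs7725821	A	G	0.187	FALSE	TRUE	FALSE	0.992
rs7729276	T	C	0.178	FALSE	TRUE	FALSE	0.96
rs7729378	C	T	0.091	FALSE	TRUE	FALSE	
rs7736675	T	C	0.154	FALSE	TRUE	FALSE	0.995
rs7737204	A	C	0.14	FALSE	TRUE	FALSE	0.941
rs7737417	T	C	0.245	FALSE	TRUE	FALSE	0.953
rs7738058	G	T	0.063	FALSE	TRUE	FALSE	0.997
rs7739341	G	A	0.148	FALSE	TRUE	FALSE	0.99
rs7740078	G	T	0.16	FALSE	TRUE	FALSE	0.929
rs7742107	A	G	0.115	FALSE	TRUE	FALSE	
rs7742679	A	G	0.14	FALSE	TRUE	FALSE	0.998
rs7747641	A	G	0.099	FALSE	TRUE	FALSE	
rs7747780	A	G	0.128	FALSE	TRUE	FALSE	0.948
rs7747817	G	T	0.056	FALSE	TRUE	FALSE	
rs7748428	C	T	0.245	FALSE	TRUE	FALSE	0.967
rs7750996	A	C	0.241	FALSE	TRUE	FALSE	
rs7752700	T	C	0.148	FALSE	TRUE	FALSE	
rs7752820	G	A	0.23	FALSE	TRUE	FALSE	0.981
rs7755177	G	T	0.141	FALSE	TRUE	FALSE	0.995
rs7757709	A	G	0.102	FALSE	TRUE	FALSE	0.917
rs7761457	G	A	0.217	FALSE	TRUE	FALSE	0.913
rs7762630	A	G	0.085	FALSE	TRUE	FALSE	
rs7762989	T	C	0.146	FALSE	TRUE	FALSE	0.96
rs7767851	A	C	0.144	FALSE	TRUE	FALSE	0.994
rs7771446	A	G	0.119	FALSE	TRUE	FALSE	0.986
rs7775496	A	C	0.216	FALSE	TRUE	FALSE	
rs7775546	T	C	0.185	FALSE	TRUE	FALSE	0.952
rs7776937	G	T	0.163	FALSE	TRUE	FALSE	
rs7782045	A	G	0.234	FALSE	TRUE	FALSE	0.961
rs7782509	C	T	0.135	FALSE	TRUE	FALSE	0.994
rs7787105	G	A	0.209	FALSE	TRUE	FALSE	0.926
rs7789070	G	T	0.193	FALSE	TRUE	FALSE	0.921
rs7791360	A	C	0.192	FALSE	TRUE	FALSE	0.988
rs7795418	A	C	0.209	FALSE	TRUE	FALSE	0.933
rs7797209	C	T	0.163	FALSE	TRUE	FALSE	0.987
rs11556924	C	T	0.15	FALSE	TRUE	FALSE	0.8
rs17514846	A	C	0.187	FALSE	TRUE	FALSE	0.78
rs2895811	G	A	0.052	FALSE	TRUE	FALSE	0.82
rs4773144	G	A	0.15	FALSE	TRUE	FALSE	0.75
rs10507391	A	C	0	FALSE	FALSE	TRUE	0.97
rs93155050	A	G	0	FALSE	FALSE	TRUE	0.96
rs17222842	G	A	0	FALSE	FALSE	TRUE	0.98
rs17216473	A	G	0	FALSE	FALSE	TRUE	0.95
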