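stratum,arm,treated,expected_events,nnt_printed
AFR,one_stage,473,41,47
AFR,two_stage_grs12,33,4,33
AFR,two_stage_grs51,12,3,17
LAT,one_stage,876,48,73
LAT,two_stage_grs12,31,6,22
LAT,two_stage_grs51,39,9,19
EA,one_stage,830,46,75
EA,two_stage_grs12,19,2,38
EA,two_stage_grs51,24,2,48
combined,one_stage,2179,135,68
combined,two_stage_grs12,59,11,23
combined,two_stage_grs51,30,7,18
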