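stratum,score,model,term,hr,lcl,ucl
AFR,GRS12,1a,per_sd,1.17,0.98,1.40
AFR,GRS12,1b,per_sd,1.16,0.97,1.39
AFR,GRS12,1c,per_sd,1.17,0.97,1.40
AFR,GRS12,1d,per_sd,1.20,1.00,1.44
AFR,GRS12,2a,tertile2,1.33,0.82,2.17
AFR,GRS12,2a,tertile3,1.81,1.14,2.88
AFR,GRS12,2b,tertile2,1.33,0.81,2.18
AFR,GRS12,2b,tertile3,1.78,1.12,2.83
AFR,GRS12,2c,tertile2,1.33,0.82,2.18
AFR,GRS12,2c,tertile3,1.78,1.12,2.84
AFR,GRS12,2d,tertile2,1.37,0.82,2.29
AFR,GRS12,2d,tertile3,1.86,1.15,3.01
AFR,GRS51,1a,per_sd,1.11,0.92,1.34
AFR,GRS51,1b,per_sd,1.09,0.90,1.32
AFR,GRS51,1c,per_sd,1.09,0.90,1.32
AFR,GRS51,1d,per_sd,1.14,0.94,1.39
AFR,GRS51,2a,tertile2,1.14,0.71,1.82
AFR,GRS51,2a,tertile3,1.42,0.90,2.23
AFR,GRS51,2b,tertile2,1.06,0.66,1.70
AFR,GRS51,2b,tertile3,1.34,0.85,2.11
AFR,GRS51,2c,tertile2,1.06,0.66,1.70
AFR,GRS51,2c,tertile3,1.34,0.85,2.11
AFR,GRS51,2d,tertile2,1.04,0.63,1.71
AFR,GRS51,2d,tertile3,1.49,0.93,2.39
LAT,GRS12,1a,per_sd,1.18,1.01,1.37
LAT,GRS12,1b,per_sd,1.23,1.05,1.43
LAT,GRS12,1c,per_sd,1.23,1.05,1.44
LAT,GRS12,1d,per_sd,1.19,1.01,1.40
LAT,GRS12,2a,tertile2,0.94,0.62,1.41
LAT,GRS12,2a,tertile3,1.59,1.09,2.31
LAT,GRS12,2b,tertile2,0.89,0.59,1.34
LAT,GRS12,2b,tertile3,1.68,1.15,2.45
LAT,GRS12,2c,tertile2,0.88,0.58,1.33
LAT,GRS12,2c,tertile3,1.68,1.15,2.45
LAT,GRS12,2d,tertile2,0.89,0.58,1.37
LAT,GRS12,2d,tertile3,1.52,1.02,2.25
LAT,GRS51,1a,per_sd,1.19,1.02,1.39
LAT,GRS51,1b,per_sd,1.19,1.02,1.39
LAT,GRS51,1c,per_sd,1.19,1.02,1.38
LAT,GRS51,1d,per_sd,1.16,0.99,1.36
LAT,GRS51,2a,tertile2,0.99,0.65,1.48
LAT,GRS51,2a,tertile3,1.61,1.12,2.34
LAT,GRS51,2b,tertile2,1.06,0.70,1.60
LAT,GRS51,2b,tertile3,1.54,1.06,2.24
LAT,GRS51,2c,tertile2,1.07,0.71,1.62
LAT,GRS51,2c,tertile3,1.55,1.07,2.25
LAT,GRS51,2d,tertile2,1.06,0.69,1.62
LAT,GRS51,2d,tertile3,1.40,0.95,2.06
EA,GRS12,1a,per_sd,1.09,0.93,1.29
EA,GRS12,1b,per_sd,1.10,0.93,1.30
EA,GRS12,1c,per_sd,1.10,0.94,1.30
EA,GRS12,1d,per_sd,1.07,0.91,1.28
EA,GRS12,2a,tertile2,0.87,0.57,1.33
EA,GRS12,2a,tertile3,1.19,0.79,1.79
EA,GRS12,2b,tertile2,0.95,0.62,1.46
EA,GRS12,2b,tertile3,1.27,0.84,1.92
EA,GRS12,2c,tertile2,0.96,0.63,1.47
EA,GRS12,2c,tertile3,1.27,0.84,1.92
EA,GRS12,2d,tertile2,1.01,0.65,1.57
EA,GRS12,2d,tertile3,1.19,0.77,1.83
EA,GRS51,1a,per_sd,1.20,1.02,1.41
EA,GRS51,1b,per_sd,1.24,1.05,1.46
EA,GRS51,1c,per_sd,1.23,1.04,1.46
EA,GRS51,1d,per_sd,1.18,0.99,1.40
EA,GRS51,2a,tertile2,1.33,0.87,2.03
EA,GRS51,2a,tertile3,1.48,0.98,2.25
EA,GRS51,2b,tertile2,1.36,0.89,2.09
EA,GRS51,2b,tertile3,1.57,1.04,2.39
EA,GRS51,2c,tertile2,1.34,0.88,2.06
EA,GRS51,2c,tertile3,1.56,1.02,2.36
EA,GRS51,2d,tertile2,1.37,0.88,2.12
EA,GRS51,2d,tertile3,1.43,0.93,2.22
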