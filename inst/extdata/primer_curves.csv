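gene_id,role,slope,r_squared,efficiency_pct
PP2A-1,reference,3.3887,0.9992,97.29
PP2A-2,reference,3.2503,0.995,103.08
UBA1,reference,3.4052,0.9964,96.64
UBC35,reference,3.3897,0.9986,97.25
UBC9,reference,3.3533,0.9942,98.71
UBC5,reference,3.3745,0.9964,97.85
UBC2,reference,3.3247,0.9901,99.88
Actin-3,reference,3.3131,0.9994,100.37
Actin-7,reference,3.3373,0.9968,99.36
ADF-2,reference,3.4725,0.9998,94.08
GAPDH-2,reference,3.3306,0.9993,99.64
GAPDH-1,reference,3.3546,0.9916,98.65
CYP21,reference,3.4389,0.9989,95.34
CYP1,reference,3.3217,0.9913,100.01
EF-1-a-1,reference,3.4712,0.9921,94.13
EF-1-a-2,reference,3.3183,0.9993,100.15
b-TUB-1,reference,3.349,0.9992,98.88
b-TUB-2,reference,3.2351,0.9951,103.76
a-TUB-3,reference,3.3079,0.9836,100.59
a-TUB-4,reference,3.321,0.9991,100.04
RPL13,reference,3.3075,0.9849,100.61
HSP70,reference,3.3274,0.9985,99.77
HSP90,reference,3.342,0.9933,99.17
ATP,reference,3.2106,0.9914,104.87
SAM5,reference,3.2452,0.9964,103.30
SAM2,reference,3.2324,0.9934,103.88
26S,reference,3.2378,0.9947,103.63
30S,reference,3.2976,0.9913,101.03
EIF-1A,reference,3.3032,0.9999,100.79
PAP1,target,3.3032,0.9999,100.79
TT8,target,3.3603,0.9926,98.42
ANS1,target,3.3156,0.9919,100.26
ANS2,target,3.338,0.9942,99.33
ANS3,target,3.3533,0.9968,98.71
ANS4,target,3.3239,0.9913,99.92
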