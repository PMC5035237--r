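treatment,replicate,variable,time_days,value
CC,1,yeast,1,3.45
CC,1,yeast,15,5.06
CC,1,yeast,38,4.95
CC,1,yeast,52,4.73
CC,1,yeast,80,4.36
CC,1,yeast,137,5.58
CC,1,yeast,250,4.79
CC,1,yeast,380,3.82
CC,2,yeast,1,5.48
CC,2,yeast,15,5.11
CC,2,yeast,38,4.94
CC,2,yeast,52,5.13
CC,2,yeast,80,5.24
CC,2,yeast,137,5.41
CC,2,yeast,250,5.85
CC,2,yeast,380,3.74
CI,1,yeast,1,1.78
CI,1,yeast,15,3.62
CI,1,yeast,38,4.70
CI,1,yeast,52,5.00
CI,1,yeast,80,4.68
CI,1,yeast,137,5.70
CI,1,yeast,250,5.06
CI,1,yeast,380,2.20
CI,2,yeast,1,nd
CI,2,yeast,15,5.26
CI,2,yeast,38,4.97
CI,2,yeast,52,5.12
CI,2,yeast,80,4.46
CI,2,yeast,137,5.73
CI,2,yeast,250,4.81
CI,2,yeast,380,1.78
CII,1,yeast,1,1.60
CII,1,yeast,15,5.19
CII,1,yeast,38,5.13
CII,1,yeast,52,4.99
CII,1,yeast,80,4.01
CII,1,yeast,137,4.90
CII,1,yeast,250,4.90
CII,1,yeast,380,4.62
CII,2,yeast,1,nd
CII,2,yeast,15,5.55
CII,2,yeast,38,4.66
CII,2,yeast,52,5.18
CII,2,yeast,80,4.35
CII,2,yeast,137,5.30
CII,2,yeast,250,4.75
CII,2,yeast,380,2.93
CT,1,yeast,1,3.03
CT,1,yeast,15,5.87
CT,1,yeast,38,5.02
CT,1,yeast,52,3.30
CT,1,yeast,80,4.06
CT,1,yeast,137,6.02
CT,1,yeast,250,5.39
CT,1,yeast,380,5.10
CT,2,yeast,1,3.03
CT,2,yeast,15,5.58
CT,2,yeast,38,4.99
CT,2,yeast,52,3.90
CT,2,yeast,80,3.20
CT,2,yeast,137,5.48
CT,2,yeast,250,4.45
CT,2,yeast,380,4.25
RT,1,yeast,1,3.20
RT,1,yeast,15,5.84
RT,1,yeast,38,5.42
RT,1,yeast,52,4.34
RT,1,yeast,80,3.95
RT,1,yeast,137,5.15
RT,1,yeast,250,4.70
RT,1,yeast,380,3.78
RT,2,yeast,1,3.20
RT,2,yeast,15,4.08
RT,2,yeast,38,5.15
RT,2,yeast,52,5.18
RT,2,yeast,80,4.48
RT,2,yeast,137,4.20
RT,2,yeast,250,4.92
RT,2,yeast,380,4.62
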