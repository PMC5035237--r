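treatment,replicate,variable,time_days,value
CC,1,acidity,1,0.61
CC,1,acidity,15,0.49
CC,1,acidity,38,0.37
CC,1,acidity,52,0.43
CC,1,acidity,80,0.49
CC,1,acidity,137,0.77
CC,1,acidity,250,0.44
CC,1,acidity,380,0.94
CC,2,acidity,1,0.61
CC,2,acidity,15,0.49
CC,2,acidity,38,0.38
CC,2,acidity,52,0.43
CC,2,acidity,80,0.47
CC,2,acidity,137,0.81
CC,2,acidity,250,0.71
CC,2,acidity,380,1.11
CI,1,acidity,1,2.40
CI,1,acidity,15,1.59
CI,1,acidity,38,1.53
CI,1,acidity,52,1.55
CI,1,acidity,80,1.51
CI,1,acidity,137,1.91
CI,1,acidity,250,1.75
CI,1,acidity,380,2.36
CI,2,acidity,1,2.40
CI,2,acidity,15,1.87
CI,2,acidity,38,1.50
CI,2,acidity,52,1.48
CI,2,acidity,80,1.37
CI,2,acidity,137,1.92
CI,2,acidity,250,2.02
CI,2,acidity,380,2.45
CII,1,acidity,1,1.60
CII,1,acidity,15,1.26
CII,1,acidity,38,1.20
CII,1,acidity,52,1.12
CII,1,acidity,80,1.06
CII,1,acidity,137,1.68
CII,1,acidity,250,1.47
CII,1,acidity,380,1.89
CII,2,acidity,1,1.60
CII,2,acidity,15,1.33
CII,2,acidity,38,1.18
CII,2,acidity,52,1.14
CII,2,acidity,80,1.12
CII,2,acidity,137,1.59
CII,2,acidity,250,1.55
CII,2,acidity,380,2.01
CT,1,acidity,1,0.61
CT,1,acidity,15,0.49
CT,1,acidity,38,0.40
CT,1,acidity,52,0.43
CT,1,acidity,80,0.39
CT,1,acidity,137,0.54
CT,1,acidity,250,0.46
CT,1,acidity,380,0.43
CT,2,acidity,1,0.61
CT,2,acidity,15,0.49
CT,2,acidity,38,0.40
CT,2,acidity,52,0.43
CT,2,acidity,80,0.41
CT,2,acidity,137,0.53
CT,2,acidity,250,0.50
CT,2,acidity,380,0.59
RT,1,acidity,1,0.61
RT,1,acidity,15,0.44
RT,1,acidity,38,0.40
RT,1,acidity,52,0.41
RT,1,acidity,80,0.39
RT,1,acidity,137,0.54
RT,1,acidity,250,0.44
RT,1,acidity,380,0.53
RT,2,acidity,1,0.61
RT,2,acidity,15,0.44
RT,2,acidity,38,0.31
RT,2,acidity,52,0.41
RT,2,acidity,80,0.34
RT,2,acidity,137,0.54
RT,2,acidity,250,0.38
RT,2,acidity,380,0.48
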