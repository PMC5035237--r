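treatment,replicate,variable,time_days,value
CC,1,pH,1,2.71
CC,1,pH,15,3.79
CC,1,pH,38,4.21
CC,1,pH,52,4.26
CC,1,pH,80,4.46
CC,1,pH,137,4.41
CC,1,pH,250,4.62
CC,1,pH,380,4.43
CC,2,pH,1,2.71
CC,2,pH,15,3.73
CC,2,pH,38,4.17
CC,2,pH,52,4.21
CC,2,pH,80,4.30
CC,2,pH,137,4.15
CC,2,pH,250,4.25
CC,2,pH,380,4.00
CI,1,pH,1,2.37
CI,1,pH,15,3.32
CI,1,pH,38,3.91
CI,1,pH,52,3.97
CI,1,pH,80,4.13
CI,1,pH,137,4.22
CI,1,pH,250,4.28
CI,1,pH,380,4.08
CI,2,pH,1,2.37
CI,2,pH,15,3.32
CI,2,pH,38,3.79
CI,2,pH,52,3.95
CI,2,pH,80,3.91
CI,2,pH,137,4.13
CI,2,pH,250,4.08
CI,2,pH,380,4.01
CII,1,pH,1,2.40
CII,1,pH,15,3.33
CII,1,pH,38,3.96
CII,1,pH,52,4.17
CII,1,pH,80,4.12
CII,1,pH,137,4.21
CII,1,pH,250,4.28
CII,1,pH,380,4.14
CII,2,pH,1,2.40
CII,2,pH,15,3.35
CII,2,pH,38,3.99
CII,2,pH,52,4.06
CII,2,pH,80,4.08
CII,2,pH,137,4.17
CII,2,pH,250,4.23
CII,2,pH,380,4.09
CT,1,pH,1,2.71
CT,1,pH,15,4.32
CT,1,pH,38,4.34
CT,1,pH,52,4.36
CT,1,pH,80,4.34
CT,1,pH,137,4.38
CT,1,pH,250,4.30
CT,1,pH,380,4.55
CT,2,pH,1,2.71
CT,2,pH,15,4.39
CT,2,pH,38,4.40
CT,2,pH,52,4.43
CT,2,pH,80,4.44
CT,2,pH,137,4.35
CT,2,pH,250,4.30
CT,2,pH,380,4.21
RT,1,pH,1,2.71
RT,1,pH,15,4.42
RT,1,pH,38,4.35
RT,1,pH,52,4.35
RT,1,pH,80,4.40
RT,1,pH,137,4.32
RT,1,pH,250,4.31
RT,1,pH,380,4.20
RT,2,pH,1,2.71
RT,2,pH,15,4.48
RT,2,pH,38,4.45
RT,2,pH,52,4.33
RT,2,pH,80,4.36
RT,2,pH,137,4.31
RT,2,pH,250,4.36
RT,2,pH,380,4.24
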