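country_code,eu2017,eu1998,prevalence,cf_prevalence_nosupp,pct_reduction_nosupp,prevented_nosupp,cf_prevalence_supp,pct_reduction_supp,prevented_supp
AT,Y,Y,0.71,0.53,25,279,0.57,19,209
BE,Y,Y,0.75,0.60,20,369,0.63,15,276
DK,Y,Y,1.12,0.80,28,394,0.88,21,296
FI,Y,Y,0.90,0.70,23,234,0.75,17,175
FR,Y,Y,1.16,0.93,20,3735,0.99,15,2801
DE,Y,Y,1.02,0.82,20,2893,0.87,15,2170
GR,Y,Y,0.57,0.46,18,214,0.49,14,160
IE,Y,Y,0.93,0.75,18,222,0.80,14,166
IT,Y,Y,0.57,0.43,25,1526,0.46,19,1145
LU,Y,Y,0.87,0.70,20,20,0.74,15,15
NL,Y,Y,0.82,0.55,32,962,0.62,24,721
PT,Y,Y,0.43,0.35,19,168,0.37,14,126
ES,Y,Y,0.85,0.69,18,1332,0.73,14,999
SE,Y,Y,0.79,0.64,19,315,0.67,14,237
GB,Y,Y,1.22,0.99,18,3344,1.05,14,2508
BG,Y,N,1.63,1.26,22,510,1.35,17,382
HR,Y,N,0.49,0.36,28,112,0.39,21,84
CY,Y,N,0.57,0.47,17,25,0.49,13,18
CZ,Y,N,0.73,0.59,20,306,0.62,15,230
EE,Y,N,0.90,0.70,23,58,0.75,17,43
HU,Y,N,0.64,0.54,16,193,0.56,12,145
LV,Y,N,0.82,0.64,22,77,0.68,17,58
LT,Y,N,0.82,0.64,22,115,0.69,17,86
MT,Y,N,0.92,0.76,17,13,0.80,13,10
PL,Y,N,0.77,0.61,20,1173,0.65,15,879
RO,Y,N,0.77,0.61,22,746,0.65,17,559
SK,Y,N,0.53,0.43,18,106,0.46,13,80
SI,Y,N,0.74,0.57,22,65,0.62,17,49
NO,N,N,0.84,0.57,32,312,0.63,24,234
CH,N,N,0.87,0.69,21,286,0.73,16,214
UA,N,N,1.80,0.91,49,8047,1.13,37,6035
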