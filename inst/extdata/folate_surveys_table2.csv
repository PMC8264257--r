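country_code,country_name,eu2017,eu1998,statistic_kind,value,value_unit,sd,log_sd,source,estimated_from_prevalence
AT,Austria,Y,Y,median,11.5,nmol/L,,0.77,ref23,false
BE,Belgium,Y,Y,median,13.8,nmol/L,,0.41,ref24,false
DK,Denmark,Y,Y,median,8.6,nmol/L,,0.29,ref25,false
FI,Finland,Y,Y,median,12.4,nmol/L,,0.55,ref26,false
FR,France,Y,Y,median,14.8,nmol/L,,0.58,ref27,false
DE,Germany,Y,Y,median,14.3,nmol/L,,0.41,ref28,false
GR,Greece,Y,Y,median,17.4,nmol/L,,0.69,ref29,false
IE,Ireland,Y,Y,median,16.2,nmol/L,,0.53,ref30,false
IT,Italy,Y,Y,median,10.4,nmol/L,,0.45,ref31,false
LU,Luxembourg,Y,Y,median,,nmol/L,,,values_from_CH,false
NL,Netherlands,Y,Y,median,7.3,nmol/L,,0.48,ref32;ref33,false
PT,Portugal,Y,Y,median,15.2,nmol/L,,0.42,ref34,false
ES,Spain,Y,Y,median,16.5,nmol/L,,0.51,ref35,false
SE,Sweden,Y,Y,median,15.0,nmol/L,,0.40,ref36,false
GB,United Kingdom,Y,Y,median,16.2,nmol/L,,0.54,ref30,false
BG,Bulgaria,Y,N,median,,nmol/L,,,values_from_PL,false
HR,Croatia,Y,N,median,9.1,nmol/L,,,ref37,false
CY,Cyprus,Y,N,median,,nmol/L,,,values_from_GR,false
CZ,Czech Republic,Y,N,median,14.0,nmol/L,,0.38,ref38,false
EE,Estonia,Y,N,median,12.4,nmol/L,,0.60,ref39,false
HU,Hungary,Y,N,median,19.0,nmol/L,,0.45,ref38,false
LV,Latvia,Y,N,median,,nmol/L,,,values_from_PL,false
LT,Lithuania,Y,N,median,,nmol/L,,,values_from_PL,false
MT,Malta,Y,N,median,,nmol/L,,,values_from_GR,false
PL,Poland,Y,N,median,14.3,nmol/L,,0.52,ref40,false
RO,Romania,Y,N,median,,nmol/L,,,values_from_PL,false
SK,Slovak Republic,Y,N,median,16.0,nmol/L,,0.35,ref41,false
SI,Slovenia,Y,N,median,,nmol/L,,,values_from_PL,false
NO,Norway,N,N,median,7.3,nmol/L,,0.50,ref42,false
CH,Switzerland,N,N,median,14.3,nmol/L,,0.67,ref43,false
UA,Ukraine,N,N,median,3.2,nmol/L,,,estimated_from_NTD_prevalence,true
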