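country_code,eu2017,eu1998,registry_name,first_year,last_year,total_cases,prevalence_per_1000,coverage_pct
BE,Y,Y,Antwerp,1998,2016,271,0.73,15
BE,Y,Y,Hainaut,1998,2017,194,0.79,10
DK,Y,Y,Odense,1998,2015,105,1.14,7
FR,Y,Y,Auvergne,2002,2015,170,1.05,1
FR,Y,Y,Brittany,2011,2017,321,1.31,2
FR,Y,Y,Paris,1998,2017,634,1.13,3
IT,Y,Y,Emilia Romagna,1998,2017,391,0.57,6
IT,Y,Y,Tuscany,1998,2017,317,0.56,5
IE,Y,Y,Cork and Kerry,1998,2017,210,1.16,14
IE,Y,Y,Dublin,1998,2012,255,0.70,28
IE,Y,Y,SE Ireland,1998,2016,137,1.05,10
NL,Y,Y,North Netherlands,1998,2017,291,0.81,10
GB,Y,Y,East Midlands and South Yorkshire,1998,2017,1288,1.13,8
GB,Y,Y,Northern England,2000,2017,775,1.35,4
GB,Y,Y,South West England,2005,2017,717,1.12,4
GB,Y,Y,Thames Valley,1998,2017,448,1.04,3
GB,Y,Y,Wales,1998,2017,942,1.41,4
GB,Y,Y,Wessex,1998,2017,684,1.20,4
PT,Y,Y,S. Portugal,1998,2017,156,0.43,18
ES,Y,Y,Basque,1998,2016,374,1.02,4
ES,Y,Y,Valencian Region,2007,2016,293,0.60,6
DE,Y,Y,Mainz,1998,2014,89,1.63,0
DE,Y,Y,Saxony-Anhalt,1998,2017,308,0.92,2
AT,Y,Y,Styria,1998,2014,129,0.73,11
FI,Y,Y,Finland,1998,2014,899,0.91,86
SE,Y,Y,Sweden,2007,2016,803,0.73,53
HR,Y,N,Zagreb,1998,2017,60,0.49,15
MT,Y,N,Malta,1998,2016,73,0.92,96
PL,Y,N,Wielkopolska,1999,2017,517,0.73,9
BG,Y,N,Sofia,1998,1999,40,2.07,1
HU,Y,N,Hungary,1998,2012,953,0.66,76
CZ,Y,N,Czech Republic,2000,2010,848,0.74,55
CH,N,N,Vaud,1998,2017,135,0.87,10
NO,N,N,Norway,1999,2016,907,0.84,92
UA,N,N,Ukraine,2005,2016,650,1.80,4
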