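cell_line,compound,proliferative,proliferative_sd,metric,metric_sd,area,area_sd
HCT116,Paclitaxel,0.284,0.05,0.33,0.03,0.2686,0.05
HCT116,5-FU,921,146,1762,264,1304,350
HCT116,Cytarabine,303,11.5,644,72,198.5,10.7
HCT116,Niraparib,3279,1124,5300,794,1432,42
HCT116,Etoposide,>2000,,>2000,,>2000,
HCT116,Oxaliplatin,>10000,,>2000,,>2000,
LoVo,Paclitaxel,n/a,,>8,,12.9,13.2
LoVo,5-FU,n/a,,0.0014,0.0002,688,253
LoVo,Cytarabine,14.2,0.4,15.2,9.2,14.3,0.3
LoVo,Niraparib,270,63,>400,,693,10
LoVo,Etoposide,n/a,,>80,,283,14
LoVo,Oxaliplatin,n/a,,>80,,>400,
PANC-1,Paclitaxel,1.24,0.04,1.28,0.26,1.31,0.60
PANC-1,5-FU,1361,150,>400,,738,53
PANC-1,Cytarabine,254,23.5,498,160,325,62
PANC-1,Niraparib,563,102,478,22,451,19
PANC-1,Etoposide,1982,5,1904,154,2041,9
PANC-1,Oxaliplatin,1705,170,457,162,1717,189
CFPAC-1,Paclitaxel,0.01,0.01,0.012,0.002,0.011,0.001
CFPAC-1,5-FU,328,27,71.8,18.3,286,30
CFPAC-1,Cytarabine,71.0,3.4,66.0,35.3,43.3,4.2
CFPAC-1,Niraparib,>3.2,,>80,,>80,
CFPAC-1,Etoposide,>2000,,>2000,,>400,
CFPAC-1,Oxaliplatin,>10000,,527,54,>400,
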