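model,day,density_per_mm2,se,printed_loss_percent
control,0,1695,23.3,NA
pONT,3,1233,78.2,27
pONT,7,894.5,98.4,47
pONT,21,404.3,52.9,76
pONT,56,491.7,120.4,71
OHT,7,1404,58.1,17
OHT,21,1303,64.9,23
OHT,56,1271,59.5,25
OHT,84,1298,68.4,23
OHT_contralateral,7,1359,74.7,20
OHT_contralateral,21,1485,21.9,12
OHT_contralateral,56,1283,98.2,24
OHT_contralateral,84,1462,89.7,14
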