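model,label,scenario,mean_tmax,mean_tmin,annual_rain,seasonal_rain
Baseline,,baseline,32.1,23.3,1121,289
BCC-CSM1-1,A,RCP4.5,33.1,24.4,1124,321
BCC_CSM1_1_M,B,RCP4.5,33.2,24.3,1065,249
BNU-ESM,C,RCP4.5,33.2,24.5,1249,298
CanESM2,D,RCP4.5,33.7,24.8,1264,300
CSIRO-Mk3-6-0,E,RCP4.5,33.3,25.0,1628,222
GFDL_CM3,F,RCP4.5,34.2,25.3,1300,333
GFDL-ESM2G,G,RCP4.5,33.2,24.3,1247,445
GFDL-ESM2M,H,RCP4.5,33.4,24.4,1045,228
INMCM4.0,I,RCP4.5,32.6,23.8,1084,282
IPSL-CM5A-LR,J,RCP4.5,33.7,24.9,1383,308
IPSL-CM5A-MR,K,RCP4.5,33.5,24.9,1331,319
MIROC-ESM,L,RCP4.5,33.2,24.7,1244,274
MIROC_ESM_CHEM,M,RCP4.5,33.0,24.7,1226,303
MIROC5,N,RCP4.5,33.3,24.5,1225,296
HadGEM2-CC,O,RCP4.5,33.4,24.8,1169,290
HadGEM2-ES,P,RCP4.5,33.6,25.0,1222,303
MPI-ESM-LR,Q,RCP4.5,33.4,24.6,1239,254
MPI-ESM-MR,R,RCP4.5,33.3,24.7,1438,334
MRI-CGCM3,S,RCP4.5,33.1,24.3,1213,275
NorESM1-M,T,RCP4.5,33.1,24.3,1227,314
BCC-CSM1-1,A,RCP8.5,33.4,24.7,1360,338
BCC_CSM1_1_M,B,RCP8.5,33.5,24.7,1107,253
BNU-ESM,C,RCP8.5,33.7,25.0,1331,344
CanESM2,D,RCP8.5,34.5,25.6,1661,445
CSIRO-Mk3-6-0,E,RCP8.5,34.2,25.4,1291,313
GFDL_CM3,F,RCP8.5,34.8,26.1,1908,1088
GFDL-ESM2G,G,RCP8.5,33.7,25.0,1050,257
GFDL-ESM2M,H,RCP8.5,33.8,25.0,995,198
INMCM4.0,I,RCP8.5,33.0,24.3,1046,285
IPSL-CM5A-LR,J,RCP8.5,34.6,25.5,935,169
IPSL-CM5A-MR,K,RCP8.5,34.3,25.5,1800,279
MIROC-ESM,L,RCP8.5,34.0,25.2,1265,305
MIROC_ESM_CHEM,M,RCP8.5,34.2,25.4,1346,355
MIROC5,N,RCP8.5,33.9,25.1,1896,491
HadGEM2-CC,O,RCP8.5,34.1,25.3,1284,358
HadGEM2-ES,P,RCP8.5,34.2,25.4,1200,377
MPI-ESM-LR,Q,RCP8.5,34.1,25.2,1129,268
MPI-ESM-MR,R,RCP8.5,34.1,25.2,1160,287
MRI-CGCM3,S,RCP8.5,33.6,24.7,1235,462
NorESM1-M,T,RCP8.5,33.7,24.9,1798,349
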