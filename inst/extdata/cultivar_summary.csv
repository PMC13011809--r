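name,n_output,ratio_pct,n_het,n_homo,heterozygosity,coverage
STS,1388,98.5,799,589,0.58,42.9
KSH,1372,97.4,1062,310,0.77,30.9
KNN,1366,96.9,988,378,0.72,26.3
PNK,1348,95.6,998,350,0.74,21.5
MDT,1342,95.2,865,477,0.64,23.0
MKK,1331,94.5,895,436,0.67,18.9
IYK,1318,93.5,770,548,0.58,19.2
KNG,1308,92.8,810,498,0.62,17.9
LMN,1306,92.7,990,316,0.76,21.7
CTR,1303,92.5,9,1294,0.01,23.8
HYG,1287,91.3,882,405,0.69,18.2
SWT,1278,90.7,783,495,0.61,16.0
OVL,1268,90.0,848,420,0.67,19.8
HSS,1257,89.2,784,473,0.62,16.7
MRC,1238,87.9,484,754,0.39,13.3
PMM,1185,84.1,531,654,0.45,13.2
DNC,1156,82.0,352,804,0.30,11.3
GRP,1145,81.3,496,649,0.43,13.5
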