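gene,T01_r1,T01_r2,T02_r1,T02_r2,T03_r1,T03_r2,T04_r1,T04_r2,T05_r1,T05_r2,T06_r1,T06_r2,T07_r1,T07_r2,T08_r1,T08_r2,T09_r1,T09_r2
g001,84,58,290,155,436,314,3964,1999,1588,1123,1100,586,177,178,171,181,65,57
g002,30,19,121,59,100,86,78,67,36,30,160,43,118,88,87,134,458,191
g003,245,273,29,9,1362,1510,1275,1029,50,69,3374,1524,488,439,9,5,1160,430
g004,280,343,2005,665,272,623,590,380,144,183,100,67,237,105,62,61,92,23
g005,273,111,365,127,286,146,223,207,109,172,271,115,237,106,343,440,280,358
g006,51,62,572,362,293,431,262,139,581,524,203,64,61,33,49,38,72,42
g007,312,175,915,775,277,410,808,669,646,302,700,210,595,767,604,1769,513,239
g008,97,133,136,85,61,217,205,88,128,93,256,65,182,78,145,158,172,146
g009,74,70,1657,995,4572,5349,7986,8025,1361,677,602,672,254,233,534,863,366,78
g010,127,183,253,141,155,110,441,327,133,74,220,45,75,54,148,163,255,103
g011,159,146,1114,454,256,190,304,200,513,396,1334,786,656,371,362,515,1263,801
g012,452,258,1363,910,691,605,1720,1105,804,417,2697,711,891,915,1458,1094,1206,705
g013,29,11,35,12,11,19,100,44,103,77,190,109,165,139,38,54,71,14
g014,69,50,163,51,48,53,190,113,237,85,415,89,143,123,137,209,241,86
g015,45,38,121,61,63,86,116,59,143,137,190,49,236,129,213,277,706,332
g016,95,161,197,148,203,128,213,194,183,71,317,121,195,224,207,526,737,240
g017,119,112,234,105,62,119,154,148,90,66,100,41,91,62,117,209,575,306
g018,66,29,116,33,63,48,38,36,12,9,3,4,7,1,6,12,33,14
g019,17,29,22,15,3,8,23,17,4,2,18,8,18,22,74,61,319,199
g020,354,158,416,86,577,295,542,380,433,255,892,267,822,742,479,557,837,339
g021,37,43,161,92,262,223,249,108,61,61,466,173,198,123,97,158,134,69
g022,67,35,65,17,6,35,41,34,18,16,33,19,23,39,65,131,55,47
g023,35,45,102,93,184,410,348,305,312,271,352,146,115,63,70,78,158,89
g024,304,238,428,439,307,172,595,566,428,107,444,290,378,519,346,531,552,502
g025,308,549,758,1028,812,916,549,853,356,712,1148,656,614,498,305,614,1144,171
g026,51,49,196,91,35,84,158,190,50,106,235,46,124,59,50,143,132,95
g027,27,36,245,143,44,100,168,98,162,149,528,209,719,196,86,124,72,16
g028,17,5,79,25,20,31,183,169,225,111,72,75,32,28,14,36,12,9
g029,226,138,123,141,67,187,215,146,237,90,512,217,112,187,302,684,1658,411
g030,81,65,115,62,64,56,149,99,122,120,139,54,173,83,106,161,85,45
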