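dataset,domain,nFeature,nSample,nClass,oobAccuracy
yeast,biology,8,1484,10,0.98
glass,physical,9,240,6,0.79
vote,social,16,232,2,0.97
segment,image,19,2310,7,0.98
mushroom,biology,20,8124,2,1.00
soybean,biology,35,307,19,0.93
splice,biology,60,3175,4,0.43
sonar,physical,60,208,2,0.85
madelon,artificial,500,2600,2,0.73
SRBCT,biology,2308,83,4,1.00
Leukemia1,biology,5327,72,3,0.94
DLBCL,biology,5469,77,2,0.83
Tumors_9,biology,5726,60,9,0.51
Brain_Tumor1,biology,5920,90,5,0.83
Arcene,biology,10000,100,2,0.79
Brain_Tumor2,biology,10367,50,4,0.74
Prostate_Tumor,biology,10509,102,2,0.92
Tumors_11,biology,12533,174,11,0.88
Lung_Cancer,biology,12600,203,5,0.92
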