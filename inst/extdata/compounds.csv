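# Dibenzazepine / dibenzoxazepine TRPA1 agonist series: scaffold substituent table.
# position: ring position label (1-4 on the N-side benzo ring, 7-10 on the
#   azomethine-side benzo ring); NA for the unsubstituted parents.
# bridge: atom at ring position 11 (A): O (oxazepine), CH2 (azepine), S (thiazepine).
# subset: train/test membership of the QSAR models.
# Known source-table quirks, resolved here: compound 8 substituent printed as
#   "8-COOMe2" is read as 8-COOMe; compound 13 is kept as 8-CN and compound 24
#   as 9-OMe (the structure table governs where the running text disagrees).
id,position,group,bridge,pec50,subset
1,NA,H,O,9.523,train
2,NA,H,CH2,8.523,train
3,1,COOMe,CH2,9.222,train
4,2,COOMe,CH2,9.398,train
5,3,COOMe,CH2,7.721,train
6,4,COOMe,CH2,7.509,train
7,7,COOMe,CH2,7.509,test
8,8,COOMe,CH2,7.000,train
9,9,COOMe,O,8.222,train
10,10,COOMe,O,10.301,train
11,8,Br,CH2,7.482,train
12,10,Br,CH2,8.456,train
13,8,CN,CH2,6.801,test
14,10,CN,CH2,8.796,train
15,10,CN,O,9.824,test
16,1,CN,O,10.000,test
17,10,CONH2,CH2,8.602,train
18,10,CONH2,O,10.097,train
19,1,CONH2,O,9.959,train
20,8,COOiPr,CH2,6.030,train
21,10,COOnBu,CH2,8.208,train
22,10,CONH(CH2)3OMe,CH2,8.114,train
23,10,CONEt2,CH2,7.398,train
24,9,OMe,O,7.854,train
25,9,OH,O,8.678,test
26,NA,H,S,8.046,train
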