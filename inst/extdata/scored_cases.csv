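# The 44 published cases of the acute mediastinitis cohort: observed
# outcome, the three factor scores (F1 proteinic status, F2
# inflammatory status, F3 general risk) and the published
# classification label (which follows the factor-1 rule, recovery
# predicted iff F1 > -1.4).
id,outcome,f1,f2,f3,classification
1,death,-8.61293,1.97822,2.03692,TN
2,recovery,-1.89787,1.01016,0.60735,FN
3,death,-5.67083,1.17312,3.18046,TN
4,recovery,2.96689,0.0611059,-1.30167,TP
5,death,-4.61678,0.759947,1.84367,TN
6,death,-3.58174,3.35379,2.15131,TN
7,recovery,1.24868,-0.0408765,0.219901,TP
8,recovery,-2.55507,0.0101163,-0.12325,FN
9,recovery,0.858724,0.588775,0.151806,TP
10,recovery,-1.95238,0.0573994,0.216068,FN
11,recovery,3.64292,-0.704072,-0.684944,TP
12,recovery,2.6163,-1.34394,-2.25436,TP
13,death,-4.19034,4.84986,0.915751,TN
14,recovery,1.82354,0.0636333,-1.26561,TP
15,recovery,3.03511,1.12721,-0.649727,TP
16,recovery,3.37817,-1.38079,-2.2192,TP
17,recovery,0.580244,-0.316079,-1.61708,TP
18,death,-1.56375,-2.27389,-0.389642,TN
19,death,-1.78795,-0.0187813,-0.789484,TN
20,recovery,0.57392,1.00331,-0.714067,TP
21,recovery,2.86891,-0.0531427,-1.05936,TP
22,recovery,0.343636,0.293051,0.970888,TP
23,recovery,1.14208,-0.965971,-1.6126,TP
24,recovery,5.51418,-1.06023,-3.28449,TP
25,death,-3.25473,1.29683,1.1493,TN
26,death,-2.12645,2.29104,0.529981,TN
27,recovery,2.29387,0.0084471,1.6481,TP
28,death,0.907509,-0.6706,3.7267,FP
29,recovery,1.29283,-1.69442,0.299441,TP
30,recovery,3.45795,-1.35408,-2.1628,TP
31,death,2.96653,-1.47445,-0.86775,FP
32,recovery,0.0323576,-1.55881,0.509574,TP
33,recovery,1.0745,0.26778,0.334441,TP
34,death,-2.52481,2.36734,1.19426,TN
35,recovery,1.32141,1.05543,0.824733,TP
36,recovery,1.29592,-1.62119,-2.8627,TP
37,death,-5.05654,0.832591,1.11692,TN
38,recovery,2.11607,-0.960466,-0.634111,TP
39,recovery,-1.4526,0.511999,1.41191,FN
40,recovery,-0.871523,-1.93215,-0.779669,TP
41,death,3.87668,-2.0661,-0.280317,FP
42,recovery,-1.30349,-0.759654,0.880723,TP
43,recovery,1.76721,-1.49925,-1.44593,TP
44,recovery,0.0236466,-1.21219,1.07856,TP
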