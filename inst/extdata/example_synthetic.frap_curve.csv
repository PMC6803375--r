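frame,time_s,roi_intensity,background
1,0,1.0137100000000001,0
2,0.5,0.994353,0
3,1,1.003631,0
4,1.5,1.006329,0
5,2,1.004043,0
6,2.5,0.998939,0
7,3,1.015115,0
8,3.5,0.999053,0
9,4,1.020184,0
10,4.5,0.999373,0
11,5,0.313049,0
12,5.5,0.418753,0
13,6,0.45813,0
14,6.5,0.529942,0
15,7,0.580064,0
16,7.5,0.627009,0
17,8,0.649693,0
18,8.5,0.652089,0
19,9,0.675842,0
20,9.5,0.731487,0
21,10,0.730459,0
22,10.5,0.728744,0
23,11,0.756121,0
24,11.5,0.779879,0
25,12,0.795467,0
26,12.5,0.780101,0
27,13,0.789005,0
28,13.5,0.780532,0
29,14,0.808869,0
30,14.5,0.803574,0
31,15,0.8199,0
32,15.5,0.827483,0
33,16,0.835631,0
34,16.5,0.823826,0
35,17,0.839415,0
36,17.5,0.821479,0
37,18,0.83494,0
38,18.5,0.838276,0
39,19,0.826518,0
40,19.5,0.85478,0
41,20,0.860129,0
42,20.5,0.858006,0
43,21,0.872649,0
44,21.5,0.861158,0
45,22,0.858011,0
46,22.5,0.879206,0
47,23,0.869866,0
48,23.5,0.895443,0
49,24,0.879633,0
50,24.5,0.893375,0
51,25,0.892837,0
52,25.5,0.884509,0
53,26,0.910765,0
54,26.5,0.904031,0
55,27,0.90103,0
56,27.5,0.905365,0
57,28,0.911798,0
58,28.5,0.908249,0
59,29,0.879708,0
60,29.5,0.91472,0
61,30,0.910375,0
62,30.5,0.918022,0
63,31,0.924058,0
64,31.5,0.934256,0
65,32,0.914954,0
66,32.5,0.937173,0
67,33,0.929379,0
68,33.5,0.938232,0
69,34,0.938836,0
70,34.5,0.938575,0
71,35,0.92263,0
72,35.5,0.933812,0
73,36,0.942561,0
74,36.5,0.928362,0
75,37,0.934003,0
76,37.5,0.946736,0
77,38,0.950067,0
78,38.5,0.948445,0
79,39,0.936337,0
80,39.5,0.93555,0
81,40,0.962995,0
82,40.5,0.951734,0
83,41,0.951295,0
84,41.5,0.950426,0
85,42,0.940886,0
86,42.5,0.960113,0
87,43,0.952958,0
88,43.5,0.95441,0
89,44,0.966651,0
90,44.5,0.966589,0
91,45,0.973321,0
92,45.5,0.95564,0
93,46,0.967883,0
94,46.5,0.976244,0
95,47,0.952155,0
96,47.5,0.955562,0
97,48,0.953737,0
98,48.5,0.951325,0
99,49,0.967559,0
100,49.5,0.974112,0
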