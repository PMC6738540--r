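"age_months","L","M","S"
0,1,89.5209879586399,0.0417177914110429
2,1,90.7442055743835,0.0417177914110429
4,1,91.9472313379675,0.0417177914110429
6,1,93.1304027217284,0.0417177914110429
8,1,94.2940521520198,0.0417177914110429
10,1,95.4385071684465,0.0417177914110429
12,1,96.5640905912696,0.0417177914110429
14,1,97.671120698384,0.0417177914110429
16,1,98.7599114134642,0.0417177914110429
18,1,99.8307725070962,0.0417177914110429
20,1,100.884009812967,0.0417177914110429
22,1,101.919925461473,0.0417177914110429
24,1,102.938818133429,0.0417177914110429
26,1,103.940983336949,0.0417177914110429
28,1,104.926713710983,0.0417177914110429
30,1,105.896299359482,0.0417177914110429
32,1,106.850028220713,0.0417177914110429
34,1,107.788186476878,0.0417177914110429
36,1,108.711059009882,0.0417177914110429
38,1,109.618929909922,0.0417177914110429
40,1,110.512083044442,0.0417177914110429
42,1,111.390802696061,0.0417177914110429
44,1,112.255374279197,0.0417177914110429
46,1,113.106085146422,0.0417177914110429
48,1,113.943225497027,0.0417177914110429
50,1,114.76708940189,0.0417177914110429
52,1,115.57797596052,0.0417177914110429
54,1,116.376190608143,0.0417177914110429
56,1,117.162046592848,0.0417177914110429
58,1,117.935866645165,0.0417177914110429
60,1,118.697984864979,0.0417177914110429
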