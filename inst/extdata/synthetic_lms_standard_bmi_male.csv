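"age_months","L","M","S"
0,-1.5,16.131875,0.09
2,-1.5,16.0822222222222,0.09
4,-1.5,16.0340972222222,0.09
6,-1.5,15.9875,0.09
8,-1.5,15.9424305555556,0.09
10,-1.5,15.8988888888889,0.09
12,-1.5,15.856875,0.09
14,-1.5,15.8163888888889,0.09
16,-1.5,15.7774305555556,0.09
18,-1.5,15.74,0.09
20,-1.5,15.7040972222222,0.09
22,-1.5,15.6697222222222,0.09
24,-1.5,15.636875,0.09
26,-1.5,15.6055555555556,0.09
28,-1.5,15.5757638888889,0.09
30,-1.5,15.5475,0.09
32,-1.5,15.5207638888889,0.09
34,-1.5,15.4955555555556,0.09
36,-1.5,15.471875,0.09
38,-1.5,15.4497222222222,0.09
40,-1.5,15.4290972222222,0.09
42,-1.5,15.41,0.09
44,-1.5,15.3924305555556,0.09
46,-1.5,15.3763888888889,0.09
48,-1.5,15.361875,0.09
50,-1.5,15.3488888888889,0.09
52,-1.5,15.3374305555556,0.09
54,-1.5,15.3275,0.09
56,-1.5,15.3190972222222,0.09
58,-1.5,15.3122222222222,0.09
60,-1.5,15.306875,0.09
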