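"age_months","L","M","S"
0,1,48.9609433358361,0.0450867052023121
2,1,51.2505354101443,0.0450867052023121
4,1,53.4985352182142,0.0450867052023121
6,1,55.7056985417633,0.0450867052023121
8,1,57.8727674689699,0.0450867052023121
10,1,60.00047064966,0.0450867052023121
12,1,62.0895235469982,0.0450867052023121
14,1,64.1406286859497,0.0450867052023121
16,1,66.1544758988085,0.0450867052023121
18,1,68.1317425681267,0.0450867052023121
20,1,70.0730938674217,0.0450867052023121
22,1,71.9791830000905,0.0450867052023121
24,1,73.8506514370217,0.0450867052023121
26,1,75.688129153467,0.0450867052023121
28,1,77.4922348658217,0.0450867052023121
30,1,79.2635762690601,0.0450867052023121
32,1,81.0027502756964,0.0450867052023121
34,1,82.7103432572769,0.0450867052023121
36,1,84.3869312895765,0.0450867052023121
38,1,86.0330804028688,0.0450867052023121
40,1,87.6493468388649,0.0450867052023121
42,1,89.2362773161903,0.0450867052023121
44,1,90.7944093065852,0.0450867052023121
46,1,92.3242713243888,0.0450867052023121
48,1,93.8263832323105,0.0450867052023121
50,1,95.3012565670098,0.0450867052023121
52,1,96.7493948886173,0.0450867052023121
54,1,98.1712941590484,0.0450867052023121
56,1,99.5674431548099,0.0450867052023121
58,1,100.938323920988,0.0450867052023121
60,1,102.284412274279,0.0450867052023121
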