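"age_months","L","M","S"
60,1,102.284412274279,0.0450867052023121
61,1,102.948306422505,0.0450867052023121
62,1,103.6061783643,0.0450867052023121
63,1,104.258086086275,0.0450867052023121
64,1,104.904087304016,0.0450867052023121
65,1,105.544239486478,0.0450867052023121
66,1,106.178599882025,0.0450867052023121
67,1,106.807225546236,0.0450867052023121
68,1,107.430173371654,0.0450867052023121
69,1,108.047500119623,0.0450867052023121
70,1,108.659262454413,0.0450867052023121
71,1,109.265516979812,0.0450867052023121
72,1,109.866320278402,0.0450867052023121
73,1,110.461728953761,0.0450867052023121
74,1,111.051799675808,0.0450867052023121
75,1,111.636589229591,0.0450867052023121
76,1,112.216154567789,0.0450867052023121
77,1,112.790552867244,0.0450867052023121
78,1,113.359841589866,0.0450867052023121
79,1,113.924078548269,0.0450867052023121
80,1,114.483321976543,0.0450867052023121
81,1,115.037630606578,0.0450867052023121
82,1,115.587063750407,0.0450867052023121
83,1,116.131681389054,0.0450867052023121
84,1,116.671544268442,0.0450867052023121
85,1,117.206714002905,0.0450867052023121
86,1,117.737253186953,0.0450867052023121
87,1,118.26322551594,0.0450867052023121
88,1,118.784695916349,0.0450867052023121
89,1,119.30173068647,0.0450867052023121
90,1,119.814397648284,0.0450867052023121
91,1,120.322766311438,0.0450867052023121
92,1,120.826908050255,0.0450867052023121
93,1,121.326896294768,0.0450867052023121
94,1,121.822806736868,0.0450867052023121
95,1,122.314717552679,0.0450867052023121
96,1,122.802709642382,0.0450867052023121
97,1,123.286866888754,0.0450867052023121
98,1,123.767276435755,0.0450867052023121
99,1,124.244028988596,0.0450867052023121
100,1,124.717219136728,0.0450867052023121
101,1,125.186945701322,0.0450867052023121
102,1,125.653312108798,0.0450867052023121
103,1,126.116426792054,0.0450867052023121
104,1,126.576403621044,0.0450867052023121
105,1,127.033362364402,0.0450867052023121
106,1,127.487429183762,0.0450867052023121
107,1,127.938737162445,0.0450867052023121
108,1,128.387426870055,0.0450867052023121
109,1,128.833646964491,0.0450867052023121
110,1,129.27755483266,0.0450867052023121
111,1,129.71931727101,0.0450867052023121
112,1,130.159111206672,0.0450867052023121
113,1,130.597124459659,0.0450867052023121
114,1,131.03355654605,0.0450867052023121
115,1,131.4686195215,0.0450867052023121
116,1,131.902538863665,0.0450867052023121
117,1,132.335554391171,0.0450867052023121
118,1,132.767921215678,0.0450867052023121
119,1,133.199910722175,0.0450867052023121
120,1,133.631811571057,0.0450867052023121
121,1,134.063930713576,0.0450867052023121
122,1,134.496594409985,0.0450867052023121
123,1,134.930149237052,0.0450867052023121
124,1,135.364963068474,0.0450867052023121
125,1,135.801426008211,0.0450867052023121
126,1,136.239951252642,0.0450867052023121
127,1,136.680975852831,0.0450867052023121
128,1,137.124961343002,0.0450867052023121
129,1,137.572394195571,0.0450867052023121
130,1,138.023786056724,0.0450867052023121
131,1,138.47967370975,0.0450867052023121
132,1,138.940618706028,0.0450867052023121
133,1,139.407206596065,0.0450867052023121
134,1,139.880045685313,0.0450867052023121
135,1,140.359765232091,0.0450867052023121
136,1,140.847012998078,0.0450867052023121
137,1,141.342452056028,0.0450867052023121
138,1,141.846756755282,0.0450867052023121
139,1,142.360607743949,0.0450867052023121
140,1,142.884685948227,0.0450867052023121
141,1,143.419665415324,0.0450867052023121
142,1,143.966204937785,0.0450867052023121
143,1,144.524938395127,0.0450867052023121
144,1,145.096463774533,0.0450867052023121
145,1,145.681330867304,0.0450867052023121
146,1,146.280027682498,0.0450867052023121
147,1,146.892965674464,0.0450867052023121
148,1,147.520463946663,0.0450867052023121
149,1,148.162732669552,0.0450867052023121
150,1,148.819856033679,0.0450867052023121
151,1,149.49177514757,0.0450867052023121
152,1,150.178271379274,0.0450867052023121
153,1,150.878950725033,0.0450867052023121
154,1,151.593229861631,0.0450867052023121
155,1,152.320324592671,0.0450867052023121
156,1,153.059241425089,0.0450867052023121
157,1,153.808773002361,0.0450867052023121
158,1,154.567498068156,0.0450867052023121
159,1,155.333786533525,0.0450867052023121
160,1,156.105810070395,0.0450867052023121
161,1,156.881558456409,0.0450867052023121
162,1,157.658861657919,0.0450867052023121
163,1,158.435417371134,0.0450867052023121
164,1,159.208823462219,0.0450867052023121
165,1,159.976614475066,0.0450867052023121
166,1,160.736301131755,0.0450867052023121
167,1,161.48541155586,0.0450867052023121
168,1,162.221532820647,0.0450867052023121
169,1,162.942351375404,0.0450867052023121
170,1,163.645690939771,0.0450867052023121
171,1,164.329546576348,0.0450867052023121
172,1,164.992113846934,0.0450867052023121
173,1,165.631812211818,0.0450867052023121
174,1,166.247302124218,0.0450867052023121
175,1,166.837495580417,0.0450867052023121
176,1,167.401560187699,0.0450867052023121
177,1,167.938917086482,0.0450867052023121
178,1,168.449233294021,0.0450867052023121
179,1,168.93240921383,0.0450867052023121
180,1,169.388562172454,0.0450867052023121
181,1,169.818006903688,0.0450867052023121
182,1,170.221233904447,0.0450867052023121
183,1,170.598886544462,0.0450867052023121
184,1,170.951737733736,0.0450867052023121
185,1,171.280666848285,0.0450867052023121
186,1,171.586637496479,0.0450867052023121
187,1,171.87067658479,0.0450867052023121
188,1,172.133855020778,0.0450867052023121
189,1,172.377270278539,0.0450867052023121
190,1,172.602030951792,0.0450867052023121
191,1,172.809243334565,0.0450867052023121
192,1,173,0.0450867052023121
193,1,173.175370293906,0.0450867052023121
194,1,173.336392620283,0.0450867052023121
195,1,173.484068369498,0.0450867052023121
196,1,173.619357324279,0.0450867052023121
197,1,173.743174372231,0.0450867052023121
198,1,173.8563873542,0.0450867052023121
199,1,173.959815883834,0.0450867052023121
200,1,174.054230983513,0.0450867052023121
201,1,174.140355394125,0.0450867052023121
202,1,174.218864429904,0.0450867052023121
203,1,174.290387263879,0.0450867052023121
204,1,174.3555085437,0.0450867052023121
205,1,174.41477025133,0.0450867052023121
206,1,174.46867373295,0.0450867052023121
207,1,174.517681837239,0.0450867052023121
208,1,174.562221110805,0.0450867052023121
209,1,174.602684009066,0.0450867052023121
210,1,174.639431089113,0.0450867052023121
211,1,174.672793158293,0.0450867052023121
212,1,174.703073358388,0.0450867052023121
213,1,174.730549170438,0.0450867052023121
214,1,174.755474329611,0.0450867052023121
215,1,174.77808064309,0.0450867052023121
216,1,174.7985797069,0.0450867052023121
217,1,174.817164519915,0.0450867052023121
218,1,174.834010995213,0.0450867052023121
219,1,174.849279370341,0.0450867052023121
220,1,174.863115519209,0.0450867052023121
221,1,174.875652169146,0.0450867052023121
222,1,174.887010027215,0.0450867052023121
223,1,174.8972988203,0.0450867052023121
224,1,174.906618253704,0.0450867052023121
225,1,174.915058893102,0.0450867052023121
226,1,174.922702974713,0.0450867052023121
227,1,174.929625148485,0.0450867052023121
228,1,174.935893158972,0.0450867052023121
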