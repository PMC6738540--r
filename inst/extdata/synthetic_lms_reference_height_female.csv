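"age_months","L","M","S"
60,1,118.697984864979,0.0417177914110429
61,1,119.074763821844,0.0417177914110429
62,1,119.448748853349,0.0417177914110429
63,1,119.819985913996,0.0417177914110429
64,1,120.188522119581,0.0417177914110429
65,1,120.554405839832,0.0417177914110429
66,1,120.917686796706,0.0417177914110429
67,1,121.278416168665,0.0417177914110429
68,1,121.636646701234,0.0417177914110429
69,1,121.992432824165,0.0417177914110429
70,1,122.345830775533,0.0417177914110429
71,1,122.696898733084,0.0417177914110429
72,1,123.045696953181,0.0417177914110429
73,1,123.392287917649,0.0417177914110429
74,1,123.736736488864,0.0417177914110429
75,1,124.079110073375,0.0417177914110429
76,1,124.419478794366,0.0417177914110429
77,1,124.757915673214,0.0417177914110429
78,1,125.0944968204,0.0417177914110429
79,1,125.429301635954,0.0417177914110429
80,1,125.762413019606,0.0417177914110429
81,1,126.093917590717,0.0417177914110429
82,1,126.423905918026,0.0417177914110429
83,1,126.752472759116,0.0417177914110429
84,1,127.079717309438,0.0417177914110429
85,1,127.405743460581,0.0417177914110429
86,1,127.730660067302,0.0417177914110429
87,1,128.054581222713,0.0417177914110429
88,1,128.377626540739,0.0417177914110429
89,1,128.699921444776,0.0417177914110429
90,1,129.021597461163,0.0417177914110429
91,1,129.342792515777,0.0417177914110429
92,1,129.663651231691,0.0417177914110429
93,1,129.984325225391,0.0417177914110429
94,1,130.304973398608,0.0417177914110429
95,1,130.625762222252,0.0417177914110429
96,1,130.946866008352,0.0417177914110429
97,1,131.268467165217,0.0417177914110429
98,1,131.590756430303,0.0417177914110429
99,1,131.91393307443,0.0417177914110429
100,1,132.238205070109,0.0417177914110429
101,1,132.563789215744,0.0417177914110429
102,1,132.890911206439,0.0417177914110429
103,1,133.219805640984,0.0417177914110429
104,1,133.550715953453,0.0417177914110429
105,1,133.88389425656,0.0417177914110429
106,1,134.219601082719,0.0417177914110429
107,1,134.558105007419,0.0417177914110429
108,1,134.89968213837,0.0417177914110429
109,1,135.244615452638,0.0417177914110429
110,1,135.593193963031,0.0417177914110429
111,1,135.945711694075,0.0417177914110429
112,1,136.30246644742,0.0417177914110429
113,1,136.663758336232,0.0417177914110429
114,1,137.029888068406,0.0417177914110429
115,1,137.401154959206,0.0417177914110429
116,1,137.777854655488,0.0417177914110429
117,1,138.16027655594,0.0417177914110429
118,1,138.548700915148,0.0417177914110429
119,1,138.94339562365,0.0417177914110429
120,1,139.344612661828,0.0417177914110429
121,1,139.752584232484,0.0417177914110429
122,1,140.167518585362,0.0417177914110429
123,1,140.589595556787,0.0417177914110429
124,1,141.01896185892,0.0417177914110429
125,1,141.455726165815,0.0417177914110429
126,1,141.899954057295,0.0417177914110429
127,1,142.351662896363,0.0417177914110429
128,1,142.810816730952,0.0417177914110429
129,1,143.277321325846,0.0417177914110429
130,1,143.751019444765,0.0417177914110429
131,1,144.231686515215,0.0417177914110429
132,1,144.719026818786,0.0417177914110429
133,1,145.212670356219,0.0417177914110429
134,1,145.712170538737,0.0417177914110429
135,1,146.217002854037,0.0417177914110429
136,1,146.726564645979,0.0417177914110429
137,1,147.240176131082,0.0417177914110429
138,1,147.757082751867,0.0417177914110429
139,1,148.276458937205,0.0417177914110429
140,1,148.797413303536,0.0417177914110429
141,1,149.318995289108,0.0417177914110429
142,1,149.840203167812,0.0417177914110429
143,1,150.359993341484,0.0417177914110429
144,1,150.877290762109,0.0417177914110429
145,1,151.391000290501,0.0417177914110429
146,1,151.900018758307,0.0417177914110429
147,1,152.403247467949,0.0417177914110429
148,1,152.899604842425,0.0417177914110429
149,1,153.388038925245,0.0417177914110429
150,1,153.867539431191,0.0417177914110429
151,1,154.337149061173,0.0417177914110429
152,1,154.795973818697,0.0417177914110429
153,1,155.243192100086,0.0417177914110429
154,1,155.678062373668,0.0417177914110429
155,1,156.099929312394,0.0417177914110429
156,1,156.508228296944,0.0417177914110429
157,1,156.902488259822,0.0417177914110429
158,1,157.282332892365,0.0417177914110429
159,1,157.647480283868,0.0417177914110429
160,1,157.997741103123,0.0417177914110429
161,1,158.333015466286,0.0417177914110429
162,1,158.653288660242,0.0417177914110429
163,1,158.95862590732,0.0417177914110429
164,1,159.249166365481,0.0417177914110429
165,1,159.525116558683,0.0417177914110429
166,1,159.786743425906,0.0417177914110429
167,1,160.034367165544,0.0417177914110429
168,1,160.268354035766,0.0417177914110429
169,1,160.489109252351,0.0417177914110429
170,1,160.697070104595,0.0417177914110429
171,1,160.892699388318,0.0417177914110429
172,1,161.076479233688,0.0417177914110429
173,1,161.248905385244,0.0417177914110429
174,1,161.4104819728,0.0417177914110429
175,1,161.561716795139,0.0417177914110429
176,1,161.703117123844,0.0417177914110429
177,1,161.835186022369,0.0417177914110429
178,1,161.958419165417,0.0417177914110429
179,1,162.073302135895,0.0417177914110429
180,1,162.180308170824,0.0417177914110429
181,1,162.279896323537,0.0417177914110429
182,1,162.372510006967,0.0417177914110429
183,1,162.458575881596,0.0417177914110429
184,1,162.538503051539,0.0417177914110429
185,1,162.612682532904,0.0417177914110429
186,1,162.681486960025,0.0417177914110429
187,1,162.745270496965,0.0417177914110429
188,1,162.804368923971,0.0417177914110429
189,1,162.859099870905,0.0417177914110429
190,1,162.90976317227,0.0417177914110429
191,1,162.956641320904,0.0417177914110429
192,1,163,0.0417177914110429
193,1,163.040088675411,0.0417177914110429
194,1,163.077141232544,0.0417177914110429
195,1,163.111376644202,0.0417177914110429
196,1,163.142999657708,0.0417177914110429
197,1,163.172201491405,0.0417177914110429
198,1,163.199160532207,0.0417177914110429
199,1,163.224043027338,0.0417177914110429
200,1,163.247003764613,0.0417177914110429
201,1,163.268186736753,0.0417177914110429
202,1,163.287725786194,0.0417177914110429
203,1,163.305745227663,0.0417177914110429
204,1,163.322360446538,0.0417177914110429
205,1,163.337678471591,0.0417177914110429
206,1,163.35179852127,0.0417177914110429
207,1,163.364812523045,0.0417177914110429
208,1,163.376805605768,0.0417177914110429
209,1,163.387856565229,0.0417177914110429
210,1,163.398038303363,0.0417177914110429
211,1,163.40741824173,0.0417177914110429
212,1,163.416058710044,0.0417177914110429
213,1,163.424017310621,0.0417177914110429
214,1,163.431347259717,0.0417177914110429
215,1,163.43809770676,0.0417177914110429
216,1,163.444314032518,0.0417177914110429
217,1,163.450038127277,0.0417177914110429
218,1,163.455308650061,0.0417177914110429
219,1,163.460161269982,0.0417177914110429
220,1,163.464628890708,0.0417177914110429
221,1,163.468741859088,0.0417177914110429
222,1,163.472528158883,0.0417177914110429
223,1,163.476013590549,0.0417177914110429
224,1,163.479221937956,0.0417177914110429
225,1,163.48217512292,0.0417177914110429
226,1,163.484893348339,0.0417177914110429
227,1,163.487395230714,0.0417177914110429
228,1,163.489697922792,0.0417177914110429
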