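"age_months","L","M","S"
60,-1.5,15.306875,0.11
61,-1.5,15.3047743055556,0.11
62,-1.5,15.3030555555556,0.11
63,-1.5,15.30171875,0.11
64,-1.5,15.3007638888889,0.11
65,-1.5,15.3001909722222,0.11
66,-1.5,15.3,0.11
67,-1.5,15.3001909722222,0.11
68,-1.5,15.3007638888889,0.11
69,-1.5,15.30171875,0.11
70,-1.5,15.3030555555556,0.11
71,-1.5,15.3047743055556,0.11
72,-1.5,15.306875,0.11
73,-1.5,15.3093576388889,0.11
74,-1.5,15.3122222222222,0.11
75,-1.5,15.31546875,0.11
76,-1.5,15.3190972222222,0.11
77,-1.5,15.3231076388889,0.11
78,-1.5,15.3275,0.11
79,-1.5,15.3322743055556,0.11
80,-1.5,15.3374305555556,0.11
81,-1.5,15.34296875,0.11
82,-1.5,15.3488888888889,0.11
83,-1.5,15.3551909722222,0.11
84,-1.5,15.361875,0.11
85,-1.5,15.3689409722222,0.11
86,-1.5,15.3763888888889,0.11
87,-1.5,15.38421875,0.11
88,-1.5,15.3924305555556,0.11
89,-1.5,15.4010243055556,0.11
90,-1.5,15.41,0.11
91,-1.5,15.4193576388889,0.11
92,-1.5,15.4290972222222,0.11
93,-1.5,15.43921875,0.11
94,-1.5,15.4497222222222,0.11
95,-1.5,15.4606076388889,0.11
96,-1.5,15.471875,0.11
97,-1.5,15.4835243055556,0.11
98,-1.5,15.4955555555556,0.11
99,-1.5,15.50796875,0.11
100,-1.5,15.5207638888889,0.11
101,-1.5,15.5339409722222,0.11
102,-1.5,15.5475,0.11
103,-1.5,15.5614409722222,0.11
104,-1.5,15.5757638888889,0.11
105,-1.5,15.59046875,0.11
106,-1.5,15.6055555555556,0.11
107,-1.5,15.6210243055556,0.11
108,-1.5,15.636875,0.11
109,-1.5,15.6531076388889,0.11
110,-1.5,15.6697222222222,0.11
111,-1.5,15.68671875,0.11
112,-1.5,15.7040972222222,0.11
113,-1.5,15.7218576388889,0.11
114,-1.5,15.74,0.11
115,-1.5,15.7585243055556,0.11
116,-1.5,15.7774305555556,0.11
117,-1.5,15.79671875,0.11
118,-1.5,15.8163888888889,0.11
119,-1.5,15.8364409722222,0.11
120,-1.5,15.856875,0.11
121,-1.5,15.8776909722222,0.11
122,-1.5,15.8988888888889,0.11
123,-1.5,15.92046875,0.11
124,-1.5,15.9424305555556,0.11
125,-1.5,15.9647743055556,0.11
126,-1.5,15.9875,0.11
127,-1.5,16.0106076388889,0.11
128,-1.5,16.0340972222222,0.11
129,-1.5,16.05796875,0.11
130,-1.5,16.0822222222222,0.11
131,-1.5,16.1068576388889,0.11
132,-1.5,16.131875,0.11
133,-1.5,16.1572743055556,0.11
134,-1.5,16.1830555555556,0.11
135,-1.5,16.20921875,0.11
136,-1.5,16.2357638888889,0.11
137,-1.5,16.2626909722222,0.11
138,-1.5,16.29,0.11
139,-1.5,16.3176909722222,0.11
140,-1.5,16.3457638888889,0.11
141,-1.5,16.37421875,0.11
142,-1.5,16.4030555555556,0.11
143,-1.5,16.4322743055556,0.11
144,-1.5,16.461875,0.11
145,-1.5,16.4918576388889,0.11
146,-1.5,16.5222222222222,0.11
147,-1.5,16.55296875,0.11
148,-1.5,16.5840972222222,0.11
149,-1.5,16.6156076388889,0.11
150,-1.5,16.6475,0.11
151,-1.5,16.6797743055556,0.11
152,-1.5,16.7124305555556,0.11
153,-1.5,16.74546875,0.11
154,-1.5,16.7788888888889,0.11
155,-1.5,16.8126909722222,0.11
156,-1.5,16.846875,0.11
157,-1.5,16.8814409722222,0.11
158,-1.5,16.9163888888889,0.11
159,-1.5,16.95171875,0.11
160,-1.5,16.9874305555556,0.11
161,-1.5,17.0235243055556,0.11
162,-1.5,17.06,0.11
163,-1.5,17.0968576388889,0.11
164,-1.5,17.1340972222222,0.11
165,-1.5,17.17171875,0.11
166,-1.5,17.2097222222222,0.11
167,-1.5,17.2481076388889,0.11
168,-1.5,17.286875,0.11
169,-1.5,17.3260243055556,0.11
170,-1.5,17.3655555555556,0.11
171,-1.5,17.40546875,0.11
172,-1.5,17.4457638888889,0.11
173,-1.5,17.4864409722222,0.11
174,-1.5,17.5275,0.11
175,-1.5,17.5689409722222,0.11
176,-1.5,17.6107638888889,0.11
177,-1.5,17.65296875,0.11
178,-1.5,17.6955555555556,0.11
179,-1.5,17.7385243055556,0.11
180,-1.5,17.781875,0.11
181,-1.5,17.8256076388889,0.11
182,-1.5,17.8697222222222,0.11
183,-1.5,17.91421875,0.11
184,-1.5,17.9590972222222,0.11
185,-1.5,18.0043576388889,0.11
186,-1.5,18.05,0.11
187,-1.5,18.0960243055556,0.11
188,-1.5,18.1424305555556,0.11
189,-1.5,18.18921875,0.11
190,-1.5,18.2363888888889,0.11
191,-1.5,18.2839409722222,0.11
192,-1.5,18.331875,0.11
193,-1.5,18.3801909722222,0.11
194,-1.5,18.4288888888889,0.11
195,-1.5,18.47796875,0.11
196,-1.5,18.5274305555556,0.11
197,-1.5,18.5772743055556,0.11
198,-1.5,18.6275,0.11
199,-1.5,18.6781076388889,0.11
200,-1.5,18.7290972222222,0.11
201,-1.5,18.78046875,0.11
202,-1.5,18.8322222222222,0.11
203,-1.5,18.8843576388889,0.11
204,-1.5,18.936875,0.11
205,-1.5,18.9897743055556,0.11
206,-1.5,19.0430555555556,0.11
207,-1.5,19.09671875,0.11
208,-1.5,19.1507638888889,0.11
209,-1.5,19.2051909722222,0.11
210,-1.5,19.26,0.11
211,-1.5,19.3151909722222,0.11
212,-1.5,19.3707638888889,0.11
213,-1.5,19.42671875,0.11
214,-1.5,19.4830555555556,0.11
215,-1.5,19.5397743055556,0.11
216,-1.5,19.596875,0.11
217,-1.5,19.6543576388889,0.11
218,-1.5,19.7122222222222,0.11
219,-1.5,19.77046875,0.11
220,-1.5,19.8290972222222,0.11
221,-1.5,19.8881076388889,0.11
222,-1.5,19.9475,0.11
223,-1.5,20.0072743055556,0.11
224,-1.5,20.0674305555556,0.11
225,-1.5,20.12796875,0.11
226,-1.5,20.1888888888889,0.11
227,-1.5,20.2501909722222,0.11
228,-1.5,20.311875,0.11
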