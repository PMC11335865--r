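191	62
122	5
1	75
27	17
127	116
186	85
32	90
118	195
98	58
17	177
74	166
183	77
174	62
51	71
14	3
83	75
167	21
127	158
24	147
106	171
28	179
58	16
98	45
137	122
60	161
163	188
138	94
7	141
40	180
18	19
178	2
119	57
76	6
136	148
22	15
93	83
37	24
21	91
157	185
151	161
53	141
46	95
155	190
1	154
57	139
150	121
56	181
22	194
89	102
11	60
13	118
9	10
56	103
133	95
41	10
145	184
162	60
14	169
156	20
35	18
200	32
158	137
191	18
51	60
180	77
37	93
28	70
57	110
22	24
163	115
158	166
151	158
55	125
145	156
170	121
14	186
76	174
75	62
59	76
171	38
189	94
94	43
159	27
200	10
89	32
18	137
10	7
124	93
83	176
7	115
132	66
166	62
147	118
115	130
112	162
143	8
60	144
112	141
75	14
79	180
147	19
165	96
26	31
195	55
9	21
191	170
3	124
10	145
186	122
22	91
113	140
117	130
19	75
182	82
13	143
130	99
94	142
155	38
186	154
171	51
198	155
60	26
196	129
122	137
5	137
184	65
197	12
76	42
80	157
150	5
72	73
8	11
68	59
184	180
166	28
95	31
121	156
78	75
152	178
188	92
154	96
167	130
167	61
176	188
66	67
11	8
156	27
51	135
116	32
116	22
191	169
125	38
4	130
14	139
179	76
87	30
176	133
180	90
140	92
113	105
129	153
158	11
111	118
111	190
52	31
195	157
23	84
29	171
192	1
92	64
190	102
2	80
53	82
76	58
150	8
149	130
10	1
75	200
92	56
56	89
177	103
167	147
7	195
154	55
46	84
198	114
91	200
125	56
51	199
67	16
157	107
144	143
69	81
200	27
73	63
76	111
116	121
182	184
16	67
122	72
109	171
121	151
175	173
117	38
172	127
39	107
125	128
41	19
3	75
23	96
106	65
21	15
150	18
83	67
83	159
84	161
32	190
108	114
114	66
58	197
96	127
188	72
15	192
86	109
175	34
55	200
68	48
184	6
194	1
130	139
198	20
143	83
71	192
19	52
198	175
1	121
152	74
140	16
78	178
134	2
151	157
169	126
162	151
61	124
200	65
99	75
80	70
7	108
116	98
58	82
52	137
162	169
93	190
127	44
143	80
112	75
87	114
146	159
137	78
2	83
24	190
120	109
118	126
137	152
41	144
169	129
166	31
93	87
27	72
36	170
89	24
166	3
6	190
16	70
30	60
95	160
174	188
57	29
34	67
34	76
18	17
109	139
55	84
61	65
92	166
130	18
11	155
113	57
50	183
114	161
98	176
87	121
191	25
53	138
192	115
29	37
23	22
111	39
167	105
90	40
133	158
75	137
85	100
47	79
67	77
200	147
127	51
101	165
29	114
56	182
158	1
142	148
66	24
55	22
128	41
68	65
25	134
48	61
157	51
15	156
44	84
92	129
48	6
39	160
139	127
162	78
154	72
159	95
140	42
92	6
45	86
48	73
102	183
137	124
154	192
183	149
8	143
51	101
162	75
41	79
187	96
43	39
28	188
23	195
135	66
139	20
140	173
188	112
82	197
21	156
179	129
19	102
175	83
174	74
142	103
146	63
84	96
195	189
153	19
199	39
129	92
19	184
103	77
45	182
169	63
47	63
23	90
170	147
195	116
68	53
158	99
55	148
110	45
125	195
1	122
62	163
39	154
180	36
67	193
137	119
47	38
157	154
77	49
20	14
105	196
175	151
200	18
74	140
151	77
4	24
124	78
171	50
27	175
177	161
94	199
194	10
9	150
102	185
161	94
58	3
105	75
174	122
174	36
170	95
5	83
81	45
167	182
45	131
66	185
159	8
98	155
9	149
83	5
106	15
192	197
104	89
121	46
40	194
60	200
73	111
27	94
118	24
56	199
120	139
149	73
197	195
121	45
135	30
156	114
46	52
130	6
115	143
72	1
84	159
71	187
162	160
92	146
99	27
113	81
34	45
180	26
191	198
42	6
115	55
184	22
129	62
104	24
126	20
119	154
107	150
61	47
29	79
63	36
177	136
30	144
193	149
81	92
55	157
98	126
65	177
165	136
11	164
114	104
83	81
37	41
169	25
186	139
14	191
115	186
52	169
152	143
110	140
178	146
146	6
60	15
151	99
159	122
109	61
130	14
154	184
80	175
36	147
45	85
118	183
53	31
62	191
87	107
190	86
187	150
82	73
11	184
32	63
116	27
8	4
140	6
181	87
13	9
27	151
158	33
53	44
83	133
114	4
140	130
84	18
120	125
125	18
21	182
27	11
19	186
164	116
135	39
51	125
45	159
14	27
38	93
4	93
118	120
110	8
17	45
137	147
95	119
186	67
95	14
174	175
24	177
142	106
139	93
175	63
178	36
3	184
174	82
44	185
104	28
20	36
118	180
90	180
106	135
161	200
5	168
153	123
122	184
111	185
157	65
97	112
1	84
65	12
14	44
46	7
38	47
142	46
182	91
6	38
83	184
47	183
183	47
182	146
63	81
128	194
44	65
81	169
87	88
94	160
7	159
8	16
157	145
54	83
131	68
160	56
62	100
185	90
172	96
99	125
33	123
163	25
150	36
60	93
38	50
11	79
100	114
176	67
152	80
31	140
194	87
189	154
43	71
184	187
84	6
55	112
196	58
180	165
199	85
189	106
121	15
172	21
160	9
134	163
41	57
37	117
45	153
171	158
100	85
85	82
31	72
15	21
90	153
20	13
123	59
199	154
99	83
177	171
162	158
161	40
191	99
169	3
175	123
15	162
184	43
123	35
148	181
95	179
171	135
182	118
80	78
160	189
133	36
135	144
70	2
9	162
136	184
97	141
43	195
31	150
96	65
71	142
120	25
1	34
105	92
6	63
3	72
63	83
127	66
176	137
111	167
40	51
5	53
150	140
47	4
39	186
56	79
8	71
96	178
199	108
32	99
20	64
37	61
86	123
17	47
129	16
83	95
163	3
153	8
150	4
189	172
21	99
111	38
21	50
34	188
7	1
134	192
163	64
21	164
6	189
38	12
53	1
152	150
115	164
129	52
78	126
122	138
36	83
24	76
186	55
200	154
118	19
58	163
193	191
185	77
19	159
13	159
60	106
124	1
144	108
32	117
169	178
189	112
184	181
45	14
92	198
26	90
39	15
23	142
150	158
110	179
44	116
155	186
173	42
89	30
23	39
92	59
136	29
138	156
195	158
162	52
52	75
113	91
9	23
147	48
4	21
60	171
119	98
18	200
163	155
190	49
150	55
164	55
8	19
101	172
158	13
200	116
29	127
144	56
67	83
83	99
176	170
87	199
154	182
172	116
148	7
142	17
147	99
159	83
138	189
53	122
103	7
125	44
97	5
8	52
86	47
124	176
44	186
186	8
164	125
59	119
160	53
85	186
90	32
58	98
77	183
71	51
3	14
21	167
171	106
45	98
188	163
94	138
141	7
180	40
57	119
6	76
148	136
24	37
91	21
185	157
139	57
181	56
10	9
32	200
115	163
158	151
62	75
76	59
10	200
7	10
66	132
62	166
118	147
130	115
162	112
144	60
141	112
180	79
19	147
96	165
31	26
55	195
124	3
145	10
91	22
130	117
143	13
155	198
26	60
129	196
65	184
42	76
5	150
59	68
180	184
28	166
178	152
92	188
61	167
38	125
130	4
139	14
92	140
11	158
118	111
171	29
1	192
80	2
58	76
8	150
200	75
89	56
147	167
84	46
56	125
143	144
171	109
151	121
173	175
38	117
19	41
75	3
66	114
197	58
72	188
34	175
48	68
1	194
52	19
175	198
178	78
2	134
126	169
124	61
169	162
44	127
159	146
152	137
129	169
31	166
87	93
72	27
170	36
3	166
70	16
60	30
29	57
84	55
18	130
176	98
138	53
39	111
40	90
158	133
137	75
51	127
182	56
1	158
24	66
22	55
41	128
156	15
6	48
127	139
78	162
72	154
42	140
6	92
86	45
73	48
124	137
192	154
96	187
39	43
188	28
195	23
112	188
156	21
129	179
102	19
74	174
189	195
77	103
182	45
63	169
90	23
147	170
53	68
195	125
163	62
36	180
154	157
78	124
50	171
175	27
10	194
95	170
45	81
149	9
15	106
111	73
24	118
195	197
1	72
27	99
20	126
150	107
47	61
79	29
36	63
144	30
92	81
157	55
126	98
136	165
104	114
81	83
41	37
25	169
186	115
146	178
6	146
184	154
147	36
183	118
73	82
184	11
4	8
9	13
18	125
182	21
11	27
93	38
93	4
45	17
119	95
14	95
177	24
106	142
93	139
63	175
82	174
28	104
135	106
123	153
185	111
65	157
91	182
169	81
88	87
90	185
25	163
50	38
67	176
80	152
140	31
187	184
6	84
58	196
85	199
15	121
57	41
153	45
82	85
153	90
13	20
158	162
99	191
162	15
135	171
2	70
162	9
184	136
141	97
150	31
65	96
34	1
83	63
53	5
79	56
108	199
99	32
95	83
3	163
8	153
172	189
99	21
50	21
188	34
1	7
64	163
12	38
150	152
164	115
76	24
55	186
19	118
163	58
1	124
108	144
178	169
112	189
142	23
179	110
186	155
42	173
30	89
39	23
52	162
75	52
48	147
98	119
19	8
170	176
182	154
189	138
122	53
176	124
53	160
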