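trial	block	segment	entropy	stimulus	omitted	burn_in
1	1	1	ordered	4	FALSE	TRUE
2	1	1	ordered	4	FALSE	TRUE
3	1	1	ordered	1	FALSE	TRUE
4	1	1	ordered	2	FALSE	TRUE
5	1	1	ordered	3	FALSE	TRUE
6	1	1	ordered	4	FALSE	FALSE
7	1	1	ordered	4	FALSE	FALSE
8	1	1	ordered	1	FALSE	FALSE
9	1	1	ordered	2	FALSE	FALSE
10	1	1	ordered	3	FALSE	FALSE
11	1	1	ordered	4	FALSE	FALSE
12	1	1	ordered	4	TRUE	FALSE
13	1	1	ordered	1	FALSE	FALSE
14	1	1	ordered	2	FALSE	FALSE
15	1	1	ordered	3	FALSE	FALSE
16	1	1	ordered	4	TRUE	FALSE
17	1	1	ordered	1	FALSE	FALSE
18	1	1	ordered	2	FALSE	FALSE
19	1	1	ordered	2	FALSE	FALSE
20	1	1	ordered	2	FALSE	FALSE
21	1	1	ordered	3	FALSE	FALSE
22	1	1	ordered	4	FALSE	FALSE
23	1	1	ordered	4	TRUE	FALSE
24	1	1	ordered	1	FALSE	FALSE
25	1	1	ordered	2	FALSE	FALSE
26	1	1	ordered	3	FALSE	FALSE
27	1	1	ordered	4	FALSE	FALSE
28	1	1	ordered	4	FALSE	FALSE
29	1	1	ordered	1	FALSE	FALSE
30	1	1	ordered	2	TRUE	FALSE
31	1	1	ordered	2	FALSE	FALSE
32	1	1	ordered	3	TRUE	FALSE
33	1	1	ordered	4	FALSE	FALSE
34	1	1	ordered	1	FALSE	FALSE
35	1	1	ordered	2	FALSE	FALSE
36	1	1	ordered	3	FALSE	FALSE
37	1	1	ordered	4	FALSE	FALSE
38	1	1	ordered	1	FALSE	FALSE
39	1	1	ordered	2	FALSE	FALSE
40	1	1	ordered	2	TRUE	FALSE
41	1	1	ordered	3	FALSE	FALSE
42	1	1	ordered	4	FALSE	FALSE
43	1	1	ordered	1	FALSE	FALSE
44	1	1	ordered	1	FALSE	FALSE
45	1	1	ordered	2	FALSE	FALSE
46	1	1	ordered	3	FALSE	FALSE
47	1	1	ordered	4	FALSE	FALSE
48	1	1	ordered	1	TRUE	FALSE
49	1	1	ordered	2	FALSE	FALSE
50	1	1	ordered	3	FALSE	FALSE
51	1	1	ordered	4	FALSE	FALSE
52	1	1	ordered	1	FALSE	FALSE
53	1	1	ordered	2	FALSE	FALSE
54	1	1	ordered	3	FALSE	FALSE
55	1	1	ordered	4	FALSE	FALSE
56	1	1	ordered	1	FALSE	FALSE
57	1	1	ordered	1	FALSE	FALSE
58	1	1	ordered	2	FALSE	FALSE
59	1	1	ordered	3	FALSE	FALSE
60	1	1	ordered	4	FALSE	FALSE
61	1	1	ordered	1	FALSE	FALSE
62	1	1	ordered	2	FALSE	FALSE
63	1	1	ordered	2	FALSE	FALSE
64	1	1	ordered	3	FALSE	FALSE
65	1	1	ordered	3	FALSE	FALSE
66	1	1	ordered	3	FALSE	FALSE
67	1	1	ordered	4	FALSE	FALSE
68	1	1	ordered	1	TRUE	FALSE
69	1	1	ordered	2	TRUE	FALSE
70	1	1	ordered	3	FALSE	FALSE
71	1	1	ordered	3	FALSE	FALSE
72	1	1	ordered	4	FALSE	FALSE
73	1	1	ordered	4	FALSE	FALSE
74	1	1	ordered	1	FALSE	FALSE
75	1	1	ordered	2	FALSE	FALSE
76	1	1	ordered	2	FALSE	FALSE
77	1	1	ordered	3	FALSE	FALSE
78	1	1	ordered	4	FALSE	FALSE
79	1	1	ordered	1	FALSE	FALSE
80	1	1	ordered	2	FALSE	FALSE
81	1	1	ordered	2	FALSE	FALSE
82	1	1	ordered	3	FALSE	FALSE
83	1	1	ordered	4	FALSE	FALSE
84	1	1	ordered	4	FALSE	FALSE
85	1	1	ordered	1	FALSE	FALSE
86	1	1	ordered	1	FALSE	FALSE
87	1	1	ordered	2	FALSE	FALSE
88	1	1	ordered	3	FALSE	FALSE
89	1	1	ordered	3	FALSE	FALSE
90	1	1	ordered	4	FALSE	FALSE
91	1	1	ordered	1	FALSE	FALSE
92	1	1	ordered	2	FALSE	FALSE
93	1	1	ordered	3	TRUE	FALSE
94	1	1	ordered	4	FALSE	FALSE
95	1	1	ordered	1	FALSE	FALSE
96	1	1	ordered	2	FALSE	FALSE
97	1	1	ordered	3	FALSE	FALSE
98	1	1	ordered	4	FALSE	FALSE
99	1	1	ordered	1	FALSE	FALSE
100	1	1	ordered	2	FALSE	FALSE
101	1	2	random	2	FALSE	TRUE
102	1	2	random	4	FALSE	TRUE
103	1	2	random	2	FALSE	TRUE
104	1	2	random	1	TRUE	TRUE
105	1	2	random	1	FALSE	TRUE
106	1	2	random	4	FALSE	FALSE
107	1	2	random	1	FALSE	FALSE
108	1	2	random	4	FALSE	FALSE
109	1	2	random	4	FALSE	FALSE
110	1	2	random	3	FALSE	FALSE
111	1	2	random	2	FALSE	FALSE
112	1	2	random	2	FALSE	FALSE
113	1	2	random	1	FALSE	FALSE
114	1	2	random	2	FALSE	FALSE
115	1	2	random	1	TRUE	FALSE
116	1	2	random	2	FALSE	FALSE
117	1	2	random	2	FALSE	FALSE
118	1	2	random	4	FALSE	FALSE
119	1	2	random	4	FALSE	FALSE
120	1	2	random	1	FALSE	FALSE
121	1	2	random	2	FALSE	FALSE
122	1	2	random	4	FALSE	FALSE
123	1	2	random	1	FALSE	FALSE
124	1	2	random	2	TRUE	FALSE
125	1	2	random	1	FALSE	FALSE
126	1	2	random	2	FALSE	FALSE
127	1	2	random	4	FALSE	FALSE
128	1	2	random	3	TRUE	FALSE
129	1	2	random	1	FALSE	FALSE
130	1	2	random	2	FALSE	FALSE
131	1	2	random	2	FALSE	FALSE
132	1	2	random	3	FALSE	FALSE
133	1	2	random	4	FALSE	FALSE
134	1	2	random	4	FALSE	FALSE
135	1	2	random	2	FALSE	FALSE
136	1	2	random	1	FALSE	FALSE
137	1	2	random	4	FALSE	FALSE
138	1	2	random	3	FALSE	FALSE
139	1	2	random	1	FALSE	FALSE
140	1	2	random	3	FALSE	FALSE
141	1	2	random	3	FALSE	FALSE
142	1	2	random	3	FALSE	FALSE
143	1	2	random	3	FALSE	FALSE
144	1	2	random	4	FALSE	FALSE
145	1	2	random	2	FALSE	FALSE
146	1	2	random	1	FALSE	FALSE
147	1	2	random	1	FALSE	FALSE
148	1	2	random	4	TRUE	FALSE
149	1	2	random	2	FALSE	FALSE
150	1	2	random	2	FALSE	FALSE
151	1	2	random	2	FALSE	FALSE
152	1	2	random	1	FALSE	FALSE
153	1	2	random	4	FALSE	FALSE
154	1	2	random	4	TRUE	FALSE
155	1	2	random	4	FALSE	FALSE
156	1	2	random	4	FALSE	FALSE
157	1	2	random	1	FALSE	FALSE
158	1	2	random	1	FALSE	FALSE
159	1	2	random	2	FALSE	FALSE
160	1	2	random	3	FALSE	FALSE
161	1	2	random	1	FALSE	FALSE
162	1	2	random	2	FALSE	FALSE
163	1	2	random	3	FALSE	FALSE
164	1	2	random	2	FALSE	FALSE
165	1	2	random	1	FALSE	FALSE
166	1	2	random	3	TRUE	FALSE
167	1	2	random	3	FALSE	FALSE
168	1	2	random	2	FALSE	FALSE
169	1	2	random	4	FALSE	FALSE
170	1	2	random	2	FALSE	FALSE
171	1	2	random	1	FALSE	FALSE
172	1	2	random	2	FALSE	FALSE
173	1	2	random	1	FALSE	FALSE
174	1	2	random	1	FALSE	FALSE
175	1	2	random	4	FALSE	FALSE
176	1	2	random	4	FALSE	FALSE
177	1	2	random	1	FALSE	FALSE
178	1	2	random	3	FALSE	FALSE
179	1	2	random	4	FALSE	FALSE
180	1	2	random	2	TRUE	FALSE
181	1	2	random	4	FALSE	FALSE
182	1	2	random	2	TRUE	FALSE
183	1	2	random	3	FALSE	FALSE
184	1	2	random	3	FALSE	FALSE
185	1	2	random	2	FALSE	FALSE
186	1	2	random	2	FALSE	FALSE
187	1	2	random	1	FALSE	FALSE
188	1	2	random	1	TRUE	FALSE
189	1	2	random	4	FALSE	FALSE
190	1	2	random	4	FALSE	FALSE
191	1	2	random	3	FALSE	FALSE
192	1	2	random	3	FALSE	FALSE
193	1	2	random	2	FALSE	FALSE
194	1	2	random	2	FALSE	FALSE
195	1	2	random	3	FALSE	FALSE
196	1	2	random	1	FALSE	FALSE
197	1	2	random	2	FALSE	FALSE
198	1	2	random	3	FALSE	FALSE
199	1	2	random	1	FALSE	FALSE
200	1	2	random	4	FALSE	FALSE
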