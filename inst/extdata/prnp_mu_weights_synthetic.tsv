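gene_id	codon	mu
PRNP_SYN	1	1
PRNP_SYN	2	1
PRNP_SYN	3	1
PRNP_SYN	4	1
PRNP_SYN	5	1
PRNP_SYN	6	1
PRNP_SYN	7	1
PRNP_SYN	8	1
PRNP_SYN	9	1
PRNP_SYN	10	1
PRNP_SYN	11	1
PRNP_SYN	12	1
PRNP_SYN	13	1
PRNP_SYN	14	1
PRNP_SYN	15	1
PRNP_SYN	16	1
PRNP_SYN	17	1
PRNP_SYN	18	1
PRNP_SYN	19	1
PRNP_SYN	20	1
PRNP_SYN	21	1
PRNP_SYN	22	1
PRNP_SYN	23	1
PRNP_SYN	24	1
PRNP_SYN	25	1
PRNP_SYN	26	1
PRNP_SYN	27	1
PRNP_SYN	28	1
PRNP_SYN	29	1
PRNP_SYN	30	1
PRNP_SYN	31	1
PRNP_SYN	32	1
PRNP_SYN	33	1
PRNP_SYN	34	1
PRNP_SYN	35	1
PRNP_SYN	36	1
PRNP_SYN	37	1
PRNP_SYN	38	1
PRNP_SYN	39	1
PRNP_SYN	40	1
PRNP_SYN	41	1
PRNP_SYN	42	1
PRNP_SYN	43	1
PRNP_SYN	44	1
PRNP_SYN	45	1
PRNP_SYN	46	1
PRNP_SYN	47	1
PRNP_SYN	48	1
PRNP_SYN	49	1
PRNP_SYN	50	1
PRNP_SYN	51	1
PRNP_SYN	52	1
PRNP_SYN	53	1
PRNP_SYN	54	1
PRNP_SYN	55	1
PRNP_SYN	56	1
PRNP_SYN	57	1
PRNP_SYN	58	1
PRNP_SYN	59	1
PRNP_SYN	60	1
PRNP_SYN	61	1
PRNP_SYN	62	1
PRNP_SYN	63	1
PRNP_SYN	64	1
PRNP_SYN	65	1
PRNP_SYN	66	1
PRNP_SYN	67	1
PRNP_SYN	68	1
PRNP_SYN	69	1
PRNP_SYN	70	1
PRNP_SYN	71	1
PRNP_SYN	72	1
PRNP_SYN	73	1
PRNP_SYN	74	1
PRNP_SYN	75	1
PRNP_SYN	76	1
PRNP_SYN	77	1
PRNP_SYN	78	1
PRNP_SYN	79	1
PRNP_SYN	80	1
PRNP_SYN	81	1
PRNP_SYN	82	1
PRNP_SYN	83	1
PRNP_SYN	84	1
PRNP_SYN	85	1
PRNP_SYN	86	1
PRNP_SYN	87	1
PRNP_SYN	88	1
PRNP_SYN	89	1
PRNP_SYN	90	1
PRNP_SYN	91	1
PRNP_SYN	92	1
PRNP_SYN	93	1
PRNP_SYN	94	1
PRNP_SYN	95	1
PRNP_SYN	96	1
PRNP_SYN	97	1
PRNP_SYN	98	1
PRNP_SYN	99	1
PRNP_SYN	100	1
PRNP_SYN	101	1
PRNP_SYN	102	1
PRNP_SYN	103	1
PRNP_SYN	104	1
PRNP_SYN	105	1
PRNP_SYN	106	1
PRNP_SYN	107	1
PRNP_SYN	108	1
PRNP_SYN	109	1
PRNP_SYN	110	1
PRNP_SYN	111	1
PRNP_SYN	112	1
PRNP_SYN	113	1
PRNP_SYN	114	1
PRNP_SYN	115	1
PRNP_SYN	116	1
PRNP_SYN	117	1
PRNP_SYN	118	1
PRNP_SYN	119	1
PRNP_SYN	120	1
PRNP_SYN	121	1
PRNP_SYN	122	1
PRNP_SYN	123	1
PRNP_SYN	124	1
PRNP_SYN	125	1
PRNP_SYN	126	1
PRNP_SYN	127	1
PRNP_SYN	128	1
PRNP_SYN	129	1
PRNP_SYN	130	1
PRNP_SYN	131	1
PRNP_SYN	132	1
PRNP_SYN	133	1
PRNP_SYN	134	1
PRNP_SYN	135	1
PRNP_SYN	136	1
PRNP_SYN	137	1
PRNP_SYN	138	1
PRNP_SYN	139	1
PRNP_SYN	140	1
PRNP_SYN	141	1
PRNP_SYN	142	1
PRNP_SYN	143	1
PRNP_SYN	144	1
PRNP_SYN	145	1
PRNP_SYN	146	1
PRNP_SYN	147	1
PRNP_SYN	148	1
PRNP_SYN	149	1
PRNP_SYN	150	1
PRNP_SYN	151	1
PRNP_SYN	152	1
PRNP_SYN	153	1
PRNP_SYN	154	1
PRNP_SYN	155	1
PRNP_SYN	156	1
PRNP_SYN	157	1
PRNP_SYN	158	1
PRNP_SYN	159	1
PRNP_SYN	160	1
PRNP_SYN	161	1
PRNP_SYN	162	1
PRNP_SYN	163	1
PRNP_SYN	164	1
PRNP_SYN	165	1
PRNP_SYN	166	1
PRNP_SYN	167	1
PRNP_SYN	168	1
PRNP_SYN	169	1
PRNP_SYN	170	1
PRNP_SYN	171	1
PRNP_SYN	172	1
PRNP_SYN	173	1
PRNP_SYN	174	1
PRNP_SYN	175	1
PRNP_SYN	176	1
PRNP_SYN	177	1
PRNP_SYN	178	1
PRNP_SYN	179	1
PRNP_SYN	180	1
PRNP_SYN	181	1
PRNP_SYN	182	1
PRNP_SYN	183	1
PRNP_SYN	184	1
PRNP_SYN	185	1
PRNP_SYN	186	1
PRNP_SYN	187	1
PRNP_SYN	188	1
PRNP_SYN	189	1
PRNP_SYN	190	1
PRNP_SYN	191	1
PRNP_SYN	192	1
PRNP_SYN	193	1
PRNP_SYN	194	1
PRNP_SYN	195	1
PRNP_SYN	196	1
PRNP_SYN	197	1
PRNP_SYN	198	1
PRNP_SYN	199	1
PRNP_SYN	200	1
PRNP_SYN	201	1
PRNP_SYN	202	1
PRNP_SYN	203	1
PRNP_SYN	204	1
PRNP_SYN	205	1
PRNP_SYN	206	1
PRNP_SYN	207	1
PRNP_SYN	208	1
PRNP_SYN	209	1
PRNP_SYN	210	1
PRNP_SYN	211	1
PRNP_SYN	212	1
PRNP_SYN	213	1
PRNP_SYN	214	1
PRNP_SYN	215	1
PRNP_SYN	216	1
PRNP_SYN	217	1
PRNP_SYN	218	1
PRNP_SYN	219	1
PRNP_SYN	220	1
PRNP_SYN	221	1
PRNP_SYN	222	1
PRNP_SYN	223	1
PRNP_SYN	224	1
PRNP_SYN	225	1
PRNP_SYN	226	1
PRNP_SYN	227	1
PRNP_SYN	228	1
PRNP_SYN	229	1
PRNP_SYN	230	1
PRNP_SYN	231	1
PRNP_SYN	232	1
PRNP_SYN	233	1
PRNP_SYN	234	1
PRNP_SYN	235	1
PRNP_SYN	236	1
PRNP_SYN	237	1
PRNP_SYN	238	1
PRNP_SYN	239	1
PRNP_SYN	240	1
PRNP_SYN	241	1
PRNP_SYN	242	1
PRNP_SYN	243	1
PRNP_SYN	244	1
PRNP_SYN	245	1
PRNP_SYN	246	1
PRNP_SYN	247	1
PRNP_SYN	248	1
PRNP_SYN	249	1
PRNP_SYN	250	1
PRNP_SYN	251	1
PRNP_SYN	252	1
PRNP_SYN	253	1
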