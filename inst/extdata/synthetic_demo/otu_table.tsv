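sample	OTU001	OTU002	OTU003	OTU004	OTU005	OTU006	OTU007	OTU008	OTU009	OTU010	OTU011	OTU012	OTU013	OTU014	OTU015	OTU016	OTU017	OTU018	OTU019	OTU020	OTU021	OTU022	OTU023	OTU024	OTU025	OTU026	OTU027	OTU028	OTU029	OTU030	OTU031	OTU032	OTU033	OTU034	OTU035	OTU036	OTU037	OTU038	OTU039	OTU040	OTU041	OTU042	OTU043	OTU044	OTU045	OTU046	OTU047	OTU048	OTU049	OTU050	OTU051	OTU052	OTU053	OTU054	OTU055	OTU056	OTU057	OTU058	OTU059	OTU060	OTU061	OTU062	OTU063	OTU064	OTU065	OTU066	OTU067	OTU068	OTU069	OTU070	OTU071	OTU072	OTU073	OTU074	OTU075	OTU076	OTU077	OTU078	OTU079	OTU080	OTU081	OTU082	OTU083	OTU084	OTU085	OTU086	OTU087	OTU088	OTU089	OTU090	OTU091	OTU092	OTU093	OTU094	OTU095	OTU096	OTU097	OTU098	OTU099	OTU100
S01	759	991	1144	779	669	613	787	774	1302	753	710	555	912	389	888	1343	681	585	805	842	588	658	541	390	821	24	27	25	37	36	28	39	26	25	32	35	18	19	33	34	27	27	18	30	18	32	38	26	20	28	84	123	159	83	86	143	127	125	118	133	92	112	133	94	40	59	101	220	117	91	81	81	92	112	93	251	197	309	162	215	307	266	183	153	198	177	294	242	266	259	214	247	172	424	185	417	425	172	167	213
S02	133	85	103	122	60	170	132	95	129	196	121	128	138	136	180	109	101	96	231	130	92	78	124	80	87	624	746	605	473	689	740	730	858	760	736	620	642	1047	666	979	601	665	1086	675	467	663	530	617	547	874	110	157	100	117	113	106	57	82	236	81	63	121	98	56	160	61	100	76	112	139	88	117	81	48	66	270	209	267	226	242	302	285	180	103	304	144	196	191	339	254	160	302	161	162	178	163	199	194	319	204
S03	595	439	536	450	298	415	593	509	253	446	752	726	524	396	327	674	557	408	958	473	251	459	484	504	404	233	648	296	295	238	252	339	239	320	168	220	172	250	207	229	266	287	335	242	389	358	177	319	388	178	39	69	30	39	28	25	22	29	40	47	62	86	36	50	48	30	27	56	44	41	26	26	54	40	36	234	268	467	190	297	401	273	333	427	343	234	397	227	496	318	321	476	395	180	415	328	277	281	398	313
S04	449	603	730	510	488	444	726	523	550	326	483	328	551	528	434	453	528	497	344	767	509	630	407	303	553	43	75	89	52	70	71	76	73	49	58	41	38	58	101	76	61	42	55	62	69	80	134	48	48	28	391	309	394	265	207	226	237	212	212	479	329	308	258	387	266	268	380	260	225	345	335	227	229	321	174	251	295	222	209	482	294	312	445	288	370	254	440	219	238	278	438	277	266	257	205	361	184	246	218	241
S05	142	455	267	349	421	403	229	328	489	412	374	272	343	271	369	305	498	333	371	554	308	199	355	428	322	158	149	250	263	227	110	177	336	166	298	184	127	248	121	265	154	110	124	224	174	180	215	412	128	137	444	413	421	365	343	252	290	309	273	201	316	520	308	395	208	352	414	231	304	208	394	265	339	227	332	507	213	526	282	272	194	367	246	236	253	292	271	285	180	485	176	281	284	194	198	210	215	122	224	424
S06	183	200	151	156	157	113	241	129	342	163	149	158	242	368	137	185	114	187	248	159	317	172	150	97	169	744	563	879	545	489	830	784	494	718	654	587	455	888	387	607	574	407	450	764	707	927	599	252	722	395	207	181	161	112	137	144	74	102	140	218	199	164	123	165	194	175	222	95	166	106	104	126	162	171	135	141	202	87	110	113	155	136	243	157	157	239	183	170	351	331	328	310	250	95	153	214	176	206	166	231
S07	327	293	283	209	361	325	381	434	235	297	284	267	428	381	307	431	359	632	333	393	480	240	581	391	352	736	544	589	323	290	470	551	410	708	455	422	589	610	256	505	473	525	486	251	465	545	515	518	632	710	235	186	130	214	185	186	218	165	237	259	122	129	193	208	221	117	178	176	141	296	161	215	130	172	222	84	69	94	62	92	75	131	123	59	131	109	139	83	153	147	140	147	112	64	93	66	58	110	100	76
S08	370	251	196	287	446	237	419	416	251	252	449	294	227	289	279	335	524	235	338	338	210	514	397	304	496	216	125	205	156	182	291	284	306	165	170	176	267	177	303	255	296	196	282	147	187	218	384	269	339	276	211	67	299	120	199	198	161	139	238	161	256	103	351	299	254	217	192	183	170	222	304	167	165	162	166	357	363	356	294	202	375	223	374	274	741	464	595	421	422	354	257	296	327	317	514	282	406	538	331	482
S09	922	1250	779	652	1158	1061	724	617	601	888	1150	1052	1157	722	858	604	930	659	737	667	822	1186	1898	679	614	70	56	104	108	125	151	130	75	68	120	125	89	86	87	121	74	125	70	126	110	101	91	94	72	53	32	45	15	23	30	39	58	18	29	30	46	39	21	36	38	42	17	31	66	40	24	34	42	41	36	125	91	108	197	116	103	94	136	135	117	100	94	118	211	96	87	191	100	88	91	67	201	231	92	116
S10	420	296	350	647	202	257	383	193	222	271	358	369	411	356	241	276	227	329	335	213	245	316	228	254	331	59	43	90	79	60	78	91	61	50	40	47	96	52	58	56	52	70	161	48	54	59	75	42	63	83	365	386	396	258	434	540	463	572	351	337	591	320	641	322	386	641	366	604	316	416	562	538	448	463	367	264	260	354	259	358	417	616	276	306	455	280	334	326	288	353	279	279	290	347	306	348	262	315	437	306
S11	439	565	814	400	554	527	345	603	455	665	387	629	757	603	474	765	677	963	886	515	757	943	733	613	720	520	232	161	210	359	215	244	348	180	178	198	241	291	293	241	330	295	114	374	324	256	205	294	154	160	105	105	163	98	138	96	49	60	126	64	97	85	111	87	187	87	131	95	144	106	77	49	71	93	50	141	205	196	137	126	148	211	126	120	140	213	170	142	140	190	228	110	147	224	127	157	128	147	211	231
S12	909	686	895	675	907	439	1051	579	651	612	1142	373	401	400	683	597	493	683	750	819	616	472	1270	701	459	82	63	56	30	31	56	52	33	53	41	40	33	34	40	35	37	33	36	34	51	28	55	41	53	42	481	271	368	295	281	382	285	328	395	353	158	520	199	368	157	511	283	275	285	303	288	254	472	274	349	128	77	59	55	65	94	76	84	93	106	92	97	68	73	223	112	120	91	69	71	127	51	84	118	75
S13	106	63	82	59	97	91	117	109	67	98	152	85	83	80	73	56	77	139	105	169	96	130	90	87	96	300	448	479	405	470	330	383	284	428	394	377	639	597	282	373	429	333	485	607	684	391	399	740	577	700	345	118	304	344	145	252	224	192	198	191	208	229	223	203	269	196	148	200	376	200	208	311	361	300	296	308	460	530	401	509	452	475	190	379	214	252	387	314	334	188	327	325	407	214	481	234	398	450	311	273
S14	202	199	287	113	169	135	149	108	317	206	170	215	193	223	206	100	237	114	144	104	174	146	109	79	140	357	399	523	366	368	542	451	484	576	394	226	324	306	233	450	392	353	349	350	338	566	389	524	504	372	224	565	447	387	328	675	515	265	410	362	290	355	296	357	440	382	378	229	301	233	530	329	311	357	211	236	226	198	175	177	145	190	168	206	210	134	218	265	137	200	207	276	236	268	173	182	239	372	207	198
S15	240	148	154	193	171	139	120	122	148	156	204	187	172	150	137	127	133	240	175	142	149	186	107	105	198	694	466	592	325	468	412	419	309	486	499	429	737	421	446	751	415	417	424	347	525	617	689	677	603	665	174	234	189	405	175	188	235	266	289	263	546	131	184	277	300	246	350	144	253	412	155	113	189	240	343	209	196	219	141	242	262	221	162	207	163	439	206	271	198	285	262	372	140	151	295	252	122	244	248	151
S16	650	503	511	412	400	762	602	688	478	671	371	494	575	629	552	418	654	443	428	503	453	480	501	373	641	189	145	175	94	177	88	173	105	217	137	172	155	200	183	110	313	184	218	152	167	138	155	99	136	278	216	447	126	236	110	211	89	173	192	131	120	114	98	142	186	113	94	162	157	174	225	113	114	197	94	334	375	219	226	291	155	276	245	468	217	191	195	600	246	161	405	369	260	209	245	248	277	463	383	351
S17	92	138	105	113	92	115	121	138	142	87	82	63	249	106	125	103	95	91	124	86	216	92	166	140	99	379	349	354	226	266	156	269	100	380	323	266	178	235	123	246	232	305	193	229	226	158	348	198	259	155	439	818	615	532	405	597	419	890	642	644	578	483	487	766	514	729	583	634	588	772	913	774	556	837	585	169	232	95	194	197	179	84	129	167	162	153	92	98	187	123	173	139	121	149	195	176	156	159	187	146
S18	33	37	25	35	37	22	27	42	38	28	37	35	34	29	39	42	21	17	36	29	26	40	41	26	33	67	53	54	95	69	83	54	88	88	75	89	54	61	81	48	88	95	50	57	73	144	191	70	47	55	392	837	277	704	311	673	495	751	470	1046	798	745	516	823	959	474	764	979	784	360	408	590	533	525	574	357	240	279	581	463	615	433	490	503	575	651	429	288	322	382	400	407	357	277	490	520	287	231	182	510
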