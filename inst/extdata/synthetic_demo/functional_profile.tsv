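sample	cbbL	beta_glu	ChiA	nifH	AOB_amoA	narG	nirK	cnorB	rubisco	pnr	dea
S01	3895041.44024676	4186015.76025909	5460996.79349333	2714594.79796871	4265726.14478552	5720449.5149179	3651327.32163264	3066258.87460556	35.835136516212	30.5501876091465	32.4078431264147
S02	354488.456740679	457951.442273884	894886.678362063	303946.129184393	522623.979963735	957187.145794144	681812.128313822	613312.682195284	8.52648171184411	5.90617449467979	5.53005324580333
S03	1242764.27720136	1370829.10504073	1875423.16417353	1234194.1435956	1523777.89012905	1500891.91160844	1948322.22198337	1637667.96821216	11.048139661113	11.4973572541993	9.62575504641823
S04	2164995.91139084	2346998.14486276	2069347.39306641	1890470.16489026	3134895.81699509	2210990.6633406	1363925.31614371	1835728.4685033	13.3377693742957	23.8697144718482	19.9944801767993
S05	1142294.43416574	1343498.93023488	2635246.03237918	1108024.59685087	1559518.15537495	1238871.28207936	1556697.56478792	1723601.2808269	14.6625568784334	28.1968297734137	18.860607305156
S06	827493.227939582	896593.474610738	794161.331572677	1230667.06491151	616205.398031153	803762.49134037	1246171.55631248	1064704.38978322	7.22637877279209	7.78529527758464	8.05254197687611
S07	5090888.23835265	5399793.78347898	3446306.88717928	4361476.93850087	4739913.33581012	4139369.82140822	8560375.39760577	7643774.14724027	55.5624835429515	31.2996899036232	44.3177888997925
S08	893346.930499065	833063.391526411	1072387.67486852	917076.327603555	1137325.06587181	1681112.97737689	1002482.6816779	1065019.84994852	10.6925824015194	6.8835322521401	7.57799709919272
S09	6126170.16498219	4953572.32503044	5905639.88043538	7391516.55268855	7348220.08525964	7354806.25595665	5890206.70735874	8018880.29724794	59.393959019163	76.350600772491	62.0724131338646
S10	530171.290288276	915542.39056267	1100656.64137708	1105883.29358979	769757.589404012	2059311.77956445	1592066.75819546	1066476.23586313	13.5481655510194	12.4308397778187	10.0016280624192
S11	6334415.72839072	2999486.32806129	4142499.96808747	4660630.71834651	2636876.75563209	2855028.46960943	2283229.05135659	5010880.9207689	22.7668562480406	43.4470190607848	35.2657966861184
S12	7363854.67006524	7796608.31985175	9148823.18905008	6867948.54647188	5412886.85671235	9899348.77664364	7697110.49231866	18031757.641314	91.4536902534431	70.1104447841659	117.09332591769
S13	224294.316086725	420802.791473071	214694.099037852	168810.7049034	314104.056305921	122442.602927669	216688.761607228	210981.981800155	3.10816372872931	1.43624275260164	2.12180551727662
S14	1054738.09095136	867775.608759949	764471.654698572	801017.511987906	1055945.86912158	977970.190098189	623587.860504432	1074313.82425519	8.58319500679427	14.1322220367919	10.324807909237
S15	1037253.10939611	844699.600266195	955821.577095648	639796.581438682	1421688.85928054	1326421.6573844	882516.135528201	1029835.55237212	13.0514478552692	11.9796728376449	14.613300552764
S16	3508690.94302847	3122312.64529341	2129997.02229054	2260573.23680957	2238582.26890883	2443947.41057062	2604254.51599225	1112008.85110562	25.7179036308701	15.4562231739303	15.2105482219927
S17	1169446.33179024	531558.78619912	714188.690092237	993527.161186501	463708.039612319	805814.864138927	934232.697957692	574611.375970705	6.04800973644078	5.72375185430634	8.22550105961928
S18	42770.5512204175	69346.5957771122	75439.4028118936	84007.3020643855	56897.4138802677	69832.5714864213	61408.3605746917	109077.672312017	0.885442111192897	0.718512400635051	0.63598807477969
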