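cone	cosLo	cosHi	C	c	F	f	dOmega	rms
1	0.958333333333333	1	0.0082987954737452	0.111423196001216	0.00265243449128645	0.0872464768528798	0.261799387799149	0.0404963324832414
2	0.916666666666667	0.958333333333333	0.00303564795452982	0.145557670171811	0.00676409442222597	0.097473888573211	0.261799387799149	0.0531312209026632
3	0.875	0.916666666666667	0	0.116436704836445	0.00820984466174483	0.106670133163052	0.261799387799149	0.0745329320362602
4	0.833333333333333	0.875	0.00731952423142421	0.11183476432718	2.58506470867123e-05	0.0216992674964425	0.261799387799149	0.0545027779449736
5	0.791666666666667	0.833333333333333	0	0.119197352702955	0.00643710072664065	0.111236257597929	0.261799387799149	0.0748984756259876
6	0.75	0.791666666666667	0.00573168602356085	0.113517661326284	0	0.121489327478385	0.261799387799149	0.0747032276962381
7	0.708333333333333	0.75	0.000334339836333752	0.198003180737307	0.0046759501197727	0.110136337043601	0.261799387799149	0.0656847444855152
8	0.666666666666667	0.708333333333333	0.000100030655335954	0.7143328477163	0.00447942943052778	0.114392215820171	0.261799387799149	0.0599778294191036
9	0.625	0.666666666666667	0	0.121190848033363	0.00401577900241483	0.115650402683614	0.261799387799149	0.0598724454416503
10	0.583333333333333	0.625	0	0.140285772477886	0.0036248781496877	0.116613173147112	0.261799387799149	0.077925449995976
11	0.541666666666667	0.583333333333333	1.04440061329559e-11	1.88702436105769e-08	0.00320501131014984	0.117311106026412	0.261799387799149	0.101814998324871
12	0.5	0.541666666666667	0.000763085910080447	0.160332425955078	0.00220910892543737	0.109265198459473	0.261799387799149	0.0763775369240613
13	0.458333333333333	0.5	0.000127792322408888	1.12730533942243	0.00266907289857445	0.119898020201675	0.261799387799149	0.0699830746533187
14	0.416666666666667	0.458333333333333	0	0.135615445804456	0.00254510592213027	0.122220777968521	0.261799387799149	0.0790962442999778
15	0.375	0.416666666666667	0	0.132893200922367	0.00234953222989457	0.125347449001054	0.261799387799149	0.0928633029496627
16	0.333333333333333	0.375	0.002093290544215	0.123105806201684	0	0.126063103884792	0.261799387799149	0.0882295531778725
17	0.291666666666667	0.333333333333333	0.00200067348787034	0.125986292542917	0	0.141083400285965	0.261799387799149	0.0839602299391186
18	0.25	0.291666666666667	0.00185028822165691	0.129085091297189	3.84277582950022e-12	1.54649317338446e-08	0.261799387799149	0.100936836839125
19	0.208333333333333	0.25	0.00173038600483912	0.130094608758394	8.74250689412153e-11	4.37003730462838e-07	0.261799387799149	0.0826797889034427
20	0.166666666666667	0.208333333333333	0	0.131246534358282	0.00163765381393966	0.129032565489654	0.261799387799149	0.101136072283824
21	0.125	0.166666666666667	0.00155324372585494	0.128842224569806	0	0.144438702213452	0.261799387799149	0.0960527115376024
22	0.0833333333333334	0.125	0	0.136690760036074	0.00146401543685684	0.131740603673564	0.261799387799149	0.0796895768297467
23	0.0416666666666667	0.0833333333333334	0.00141085885240353	0.131129694492536	0	0.134568109136929	0.261799387799149	0.0990950951085526
24	0	0.0416666666666667	0.00133538155134206	0.133720240228984	1.85551155194236e-11	8.34415174912524e-08	0.261799387799149	0.105380727720294
25	-0.0416666666666665	0	0.000416361296886443	0.166604019466651	0.000864176277440333	0.119342656239344	0.261799387799149	0.0707161644266123
26	-0.0833333333333333	-0.0416666666666665	0.00124284512187559	0.135969738074863	1.74656539779531e-09	8.07102694993745e-06	0.261799387799149	0.104326552418664
27	-0.125	-0.0833333333333333	0.00118257256875583	0.135578518664845	8.32072957834292e-12	6.80763820700973e-08	0.261799387799149	0.0898783534448255
28	-0.166666666666667	-0.125	0.00113024049336519	0.13482209357974	5.49411025809547e-12	3.76552657990234e-08	0.261799387799149	0.110158070401463
29	-0.208333333333333	-0.166666666666667	0.00111767102692847	0.137816082292357	1.22409827926638e-11	9.38636909364956e-08	0.261799387799149	0.0910233832828419
30	-0.25	-0.208333333333333	0.00108676987604839	0.134201376116521	0	0.153570580233581	0.261799387799149	0.0860634818288962
31	-0.291666666666667	-0.25	0.00107486373020081	0.138205363296389	3.95196859000349e-12	2.74008480261196e-08	0.261799387799149	0.111059143003419
32	-0.333333333333333	-0.291666666666667	0.00104574748046676	0.139351449929614	1.17497097103183e-11	9.78532191927798e-08	0.261799387799149	0.104880131134446
33	-0.375	-0.333333333333333	0.00103549455514921	0.138213922536297	1.71911296047367e-11	1.68354008532208e-07	0.261799387799149	0.0997575951943542
34	-0.416666666666667	-0.375	0.00100317345311523	0.140128601021428	2.18346620016261e-11	1.97494911836378e-07	0.261799387799149	0.0962375541025025
35	-0.458333333333333	-0.416666666666667	0.000964337559767951	0.136681676561947	0	0.164307079861479	0.261799387799149	0.110647100243689
36	-0.5	-0.458333333333333	0.00100644927148796	0.14321546547664	0	0.14321546547664	0.261799387799149	0.115562330842469
37	-0.541666666666667	-0.5	0.000986267292254421	0.14321546547664	0	0.14321546547664	0.261799387799149	0.0781396935259208
38	-0.583333333333333	-0.541666666666667	9.64669241218401e-05	1.12808594704981	0.000936042987337813	0.138565085408368	0.261799387799149	0.0820658115875183
39	-0.625	-0.583333333333333	0.000106323347702794	10.8511149941419	0.000965816922239951	0.143363223445544	0.261799387799149	0.0961921329816338
40	-0.666666666666667	-0.625	0	1.07901858337627	0.000982500994399207	0.14660491696501	0.261799387799149	0.0999631057356537
41	-0.708333333333333	-0.666666666666667	0.000935450157603493	0.14321546547664	0	0.14321546547664	0.261799387799149	0.132236073374754
42	-0.75	-0.708333333333333	5.50440151236636e-05	1.69433303438772	0.000950086121980151	0.146752382788664	0.261799387799149	0.108468008088152
43	-0.791666666666667	-0.75	0.000922880937550005	0.14321546547664	0	0.14321546547664	0.261799387799149	0.0981061654675429
44	-0.833333333333333	-0.791666666666667	0	0.207286840769752	0.000955248093192252	0.148257049833863	0.261799387799149	0.0968068892837067
45	-0.875	-0.833333333333333	5.06971067722999e-05	1.94675101651557	0.000908619512485605	0.144377406429459	0.261799387799149	0.0843326811751886
46	-0.916666666666667	-0.875	0	0.216740585512843	0.000936575083429243	0.149274870218195	0.261799387799149	0.0827161278394326
47	-0.958333333333333	-0.916666666666667	0.000137886259921349	8.40049005591871	0.000908731613223359	0.145166764242529	0.261799387799149	0.103341882263616
48	-1	-0.958333333333333	0.000167843319121007	13.5854071417121	0.000918414634286571	0.148377898711066	0.261799387799149	0.0864732395258781
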