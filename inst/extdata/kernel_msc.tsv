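cone	cosLo	cosHi	C	c	F	f	dOmega	rms
1	0.958333333333333	1	0	0.0570845701647733	0.00986295489386184	0.0432846004133409	0.261799387799149	0.0761286686974345
2	0.916666666666667	0.958333333333333	1.51239488384098e-14	3.09816468710559e-06	0.00875556495877917	0.0422363124417293	0.261799387799149	0.0777659088434074
3	0.875	0.916666666666667	0.0077722835145816	0.0410842942372891	7.89215221391139e-15	5.74627333557065e-06	0.261799387799149	0.0851655694973945
4	0.833333333333333	0.875	0.00689547766621698	0.0397803652257671	0	5.20092756258665e-06	0.261799387799149	0.089428326730814
5	0.791666666666667	0.833333333333333	0	0.0422959861336713	0.00612198128963988	0.0384901007893622	0.261799387799149	0.0968685642112598
6	0.75	0.791666666666667	0	0.0446266539074258	0.00553973318941724	0.0374030433355785	0.261799387799149	0.111446905134218
7	0.708333333333333	0.75	0	0.0452263181650102	0.00502941167393387	0.0368104749217444	0.261799387799149	0.119051577282856
8	0.666666666666667	0.708333333333333	0	0.0435270783998563	0.00462283865112155	0.0360862914879266	0.261799387799149	0.108361814466055
9	0.625	0.666666666666667	0	0.0474105128675214	0.00420735802045143	0.0352740845302161	0.261799387799149	0.12041081176241
10	0.583333333333333	0.625	0	0.0512550724593895	0.00380124836196331	0.0339871725696711	0.261799387799149	0.141151847165065
11	0.541666666666667	0.583333333333333	0	0.0475409210486103	0.00348132095311117	0.033194690597067	0.261799387799149	0.153558149325445
12	0.5	0.541666666666667	0.00313709828679412	0.0315384473528184	1.57039831224795e-14	7.88894695315118e-07	0.261799387799149	0.157314755314311
13	0.458333333333333	0.5	0.00294663752856572	0.031291346445319	0	0.031291346445319	0.261799387799149	0.1613546754611
14	0.416666666666667	0.458333333333333	0.00279896411106549	0.031291346445319	0	0.031291346445319	0.261799387799149	0.180158602550847
15	0.375	0.416666666666667	0.00263880561343778	0.031291346445319	0	0.031291346445319	0.261799387799149	0.199266678070623
16	0.333333333333333	0.375	0.0025289345000444	0.031291346445319	0	0.031291346445319	0.261799387799149	0.17553887593598
17	0.291666666666667	0.333333333333333	0.00242638412619534	0.031291346445319	0	0.031291346445319	0.261799387799149	0.214291510135245
18	0.25	0.291666666666667	0.00212981382880754	0.0286720759193587	0	0.0312515271352824	0.261799387799149	0.207990079650566
19	0.208333333333333	0.25	0	0.0293663701757235	0.00196512610620532	0.02774533603742	0.261799387799149	0.217428236631805
20	0.166666666666667	0.208333333333333	0.00181669153387188	0.0266392975937381	2.26140845428057e-16	6.07168837412468e-08	0.261799387799149	0.227954625112435
21	0.125	0.166666666666667	0	0.0308507299852499	0.00178761960273466	0.0270992577590922	0.261799387799149	0.247369729026637
22	0.0833333333333334	0.125	0	0.0310827056803574	0.00175746597404077	0.0278876092743723	0.261799387799149	0.21884048615659
23	0.0416666666666667	0.0833333333333334	0.00191945704994005	0.031291346445319	0	0.031291346445319	0.261799387799149	0.277321572469195
24	0	0.0416666666666667	0.00161101558075786	0.0271266367942205	0	0.031901030136278	0.261799387799149	0.262771791402419
25	-0.0416666666666665	0	0	0.0299351276928928	0.00165064706463902	0.0281986478862322	0.261799387799149	0.208943286954454
26	-0.0833333333333333	-0.0416666666666665	0.00154494713115216	0.0273199170233328	0	0.0299692052096813	0.261799387799149	0.242378318836228
27	-0.125	-0.0833333333333333	0.00150679402082117	0.0274972408853652	0	0.0306757776325271	0.261799387799149	0.231977175144542
28	-0.166666666666667	-0.125	0	0.0348995125217927	0.00143982474294728	0.0268358877603664	0.261799387799149	0.250220875904826
29	-0.208333333333333	-0.166666666666667	0.00142558676228201	0.0272705868371245	0	0.030020778885218	0.261799387799149	0.252458592690242
30	-0.25	-0.208333333333333	0	0.0308681112588003	0.00134639604389747	0.0262578348040938	0.261799387799149	0.282895656489463
31	-0.291666666666667	-0.25	0.0013771081974933	0.0274876627193333	0	0.0306840497131519	0.261799387799149	0.251464066735008
32	-0.333333333333333	-0.291666666666667	0.00134949685683245	0.0275980805419049	0	0.0304436666508376	0.261799387799149	0.253114722927675
33	-0.375	-0.333333333333333	0	0.0348979411871481	0.00134481418120236	0.0277499598336487	0.261799387799149	0.242722632536292
34	-0.416666666666667	-0.375	0.00129154589929203	0.0273178839298461	0	0.0290583935633309	0.261799387799149	0.269035156382169
35	-0.458333333333333	-0.416666666666667	0.00127622355306187	0.0275211260934036	0	0.0298148490573216	0.261799387799149	0.247800374948123
36	-0.5	-0.458333333333333	0.00123323326419904	0.0268648929848338	3.30692820675291e-17	3.77287518885393e-08	0.261799387799149	0.234115359154662
37	-0.541666666666667	-0.5	0.00125379317791438	0.0276162421571867	0	0.0306615582352267	0.261799387799149	0.250447200150627
38	-0.583333333333333	-0.541666666666667	0.00139720534570769	0.031291346445319	0	0.031291346445319	0.261799387799149	0.276988493389208
39	-0.625	-0.583333333333333	0.00138244959037077	0.031291346445319	0	0.031291346445319	0.261799387799149	0.244983001987724
40	-0.666666666666667	-0.625	0	0.0291508485066833	0.00126266028562417	0.0288327368277993	0.261799387799149	0.229274606787362
41	-0.708333333333333	-0.666666666666667	0.00134967654287357	0.031291346445319	0	0.031291346445319	0.261799387799149	0.249175740485445
42	-0.75	-0.708333333333333	0.00133302482772538	0.031291346445319	0	0.031291346445319	0.261799387799149	0.252065602213135
43	-0.791666666666667	-0.75	0.00132479701114349	0.031291346445319	0	0.031291346445319	0.261799387799149	0.242505780727316
44	-0.833333333333333	-0.791666666666667	0.00131128955402011	0.031291346445319	0	0.031291346445319	0.261799387799149	0.260087284478503
45	-0.875	-0.833333333333333	0.00129189020942754	0.031291346445319	0	0.031291346445319	0.261799387799149	0.239771672778855
46	-0.916666666666667	-0.875	0.00127996649647088	0.031291346445319	0	0.031291346445319	0.261799387799149	0.236666910000938
47	-0.958333333333333	-0.916666666666667	0.0012728985686684	0.031291346445319	0	0.031291346445319	0.261799387799149	0.245780030309768
48	-1	-0.958333333333333	0.00126335601311601	0.031291346445319	0	0.031291346445319	0.261799387799149	0.233572309020285
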