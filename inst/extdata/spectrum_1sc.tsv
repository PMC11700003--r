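energy	weight
0.0509505705612825	0.000176826773801506
0.0541522466131279	0.00185065140345277
0.0575551123558449	0.00161436610378218
0.061171810321363	0.00213618071197783
0.0650157774839753	0.00272201779147421
0.0691012951821958	0.000371288050026498
0.0734435421776485	0.000574006590595299
0.0780586510481182	9.03296118365447e-05
0.0829637681242757	1.66397607079245e-06
0.0881771171927588	3.00049823460018e-05
0.0937180672022832	6.74536604845909e-05
0.0996072042243286	5.91336668432865e-05
0.105866407935752	4.49357521304474e-05
0.112518932907481	0.000449142106522143
0.1195894950013	0.00124165580896751
0.127104363195709	0.00107281003952847
0.135091457182012	0.00310469556598365
0.143580451093244	0.0348735177572623
0.152602883751294	0.0381489318913287
0.162192275841838	0.0361640178715071
0.172384254452412	0.04406605857337
0.183216685436313	0.045859946563663
0.194729814094105	0.0456529612111346
0.206966414695377	0.0458262995089489
0.219971949396298	0.0481013157687627
0.233794737143352	0.0539543454093456
0.248486133190801	0.0612499477546783
0.264100719898829	0.0722559835154594
0.280696509521208	0.0857382143260634
0.298335159735923	0.0919504526299355
0.317082202719496	0.0469531601247859
0.337007288616078	0.0207171099474036
0.358184444305858	0.0240466028885894
0.380692348434199	0.028017086292326
0.404614623723276	0.0325824555266853
0.430040147652259	0.0375393668654569
0.457063382660279	0.0422087907801558
0.485784727098978	0.00979770863574117
0.516310888238514	0.0103130937062354
0.548755278712846	0.0117959557100218
0.583238437877186	0.0129236266520931
0.619888479643079	0.00239588525387436
0.658841568454929	0.000122260351105671
0.700242425176351	0.000178071214746505
0.744244864765848	0.000219903379581901
0.791012367739414	0.000243594324648908
0.840718687543206	0.000294709702899631
0.893548496092816	7.83852041096073e-05
0.949698069877505	6.20777507714759e-05
1.00937601917845	3.10849102256527e-05
1.07280406311024	2.99154012589316e-05
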