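energy	weight
0.0180801816734393	7.06356125343116e-09
0.0192163197782568	8.81044472787022e-08
0.020423851512659	5.6059136824054e-07
0.0217072631713346	2.81258878235531e-06
0.023071322962641	1.1272192512185e-05
0.0245210987237394	3.66521353719013e-05
0.0260619767489286	9.72671796797013e-05
0.0276996818011307	0.00022212911208335
0.0294402983808753	0.000447900362185113
0.0312902933318025	0.000833541196227113
0.03325653986667	0.00139972564468952
0.0353463431031282	0.00219020454368221
0.0375674672041327	0.00320763606731298
0.0399281642238312	0.00451999885919477
0.0424372047660922	0.00595539269295962
0.0451039105695813	0.00793175490622169
0.0479381891404466	0.00973063924020347
0.0509505705612825	0.0117456562503508
0.0541522466131279	0.0132897792365927
0.0575551123558449	0.0144960770748182
0.061171810321363	0.016171223485259
0.0650157774839753	0.017830513931257
0.0691012951821958	0.0200261349216839
0.0734435421776485	0.0228601805226354
0.0780586510481182	0.0254582531683063
0.0829637681242757	0.028309563721217
0.0881771171927588	0.0311262042269326
0.0937180672022832	0.0366381728351912
0.0996072042243286	0.0413232489258971
0.105866407935752	0.0447550807385801
0.112518932907481	0.0475469489756614
0.1195894950013	0.0499985889323039
0.127104363195709	0.0534243402450206
0.135091457182012	0.0588148926352467
0.143580451093244	0.0583121384511184
0.152602883751294	0.0509309723592197
0.162192275841838	0.0457922030827553
0.172384254452412	0.0403239011256817
0.183216685436313	0.0351619715270096
0.194729814094105	0.0302135777093643
0.206966414695377	0.0266945885827761
0.219971949396298	0.024033599561373
0.233794737143352	0.0219947737844209
0.248486133190801	0.0197238214367234
0.264100719898829	0.0174791614345594
0.280696509521208	0.0141970663274873
0.298335159735923	0.00997231621505096
0.317082202719496	0.00671585719115573
0.337007288616078	0.00580682370752308
0.358184444305858	0.00552461856118051
0.380692348434199	0.00478356120351795
0.404614623723276	0.00406889609858552
0.430040147652259	0.00299295242369081
0.457063382660279	0.00190506878838746
0.485784727098978	0.00108876437074935
0.516310888238514	0.000860096815744289
0.548755278712846	0.000623343499181683
0.583238437877186	0.000291780739018195
0.619888479643079	2.12286501902371e-05
0.658841568454929	2.15473011181562e-05
0.700242425176351	1.8705338168513e-05
0.744244864765848	2.19069788106092e-05
0.791012367739414	1.57571142395797e-05
0.840718687543206	6.55731376158926e-06
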