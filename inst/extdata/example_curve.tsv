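# curve_id=v000500_c00001
# velocity_nm_s=500
# k_c_pN_nm=30
# sample_step_nm=0.2
# temperature_K=298
# gt_bound=1
# gt_nonspecific=0
# gt_truncated=0
# gt_rupture_force_pN=76.9228004860452
# gt_rupture_separation_nm=9.23590665046516
# gt_loading_rate_pN_s=11556.262837873
piezo_nm	trace_force_pN	retrace_force_pN
-3.4	95.4580827781086	103.943854709993
-3.2	93.9943637745549	92.228685689385
-3	92.3616678177091	96.514324570665
-2.8	90.9745715319489	76.3900278714848
-2.6	73.5224699344641	69.0026200769989
-2.4	69.7344067089185	60.9349521575073
-2.2	68.834748598212	69.1039913419763
-2	63.788687493383	50.9575092173624
-1.8	54.1388708668556	40.7125973704207
-1.6	43.4267143736557	47.2111757652929
-1.4	47.9256662523833	43.8913481793091
-1.2	30.7483415288757	34.3807377723258
-1	29.7469690722047	31.8841605627792
-0.8	25.0213793384795	27.0205308316311
-0.6	20.6056429504657	21.4755183106962
-0.4	15.2090186119554	14.2662190998394
-0.2	1.94974416792278	15.5615508663055
0	-8.19261197651708	-1.48028378726496
0.2	6.25887691644877	1.27652992177188
0.4	-3.32755951058691	8.99917009106795
0.6	2.37024901491909	-9.32614298557444
0.8	-0.0746531715925272	-1.58349075629878
1	-4.88990765609936	-6.14003161346999
1.2	4.83508885718018	3.62217945369349
1.4	-5.99610384102681	-10.1360085857675
1.6	-1.5130258795498	-4.6642249145253
1.8	-4.70122278690673	5.36364419099413
2	4.01719938740785	0.609512508760112
2.2	-1.78649115705478	-6.62775650480111
2.4	1.6865882852318	-10.9058385378315
2.6	4.4486539860148	-14.8338545756842
2.8	2.45706389807802	-6.9333095778012
3	2.90370263391253	-8.62840709115314
3.2	-8.64314925038597	0.996703959352613
3.4	0.317535729475863	-6.59727334058089
3.6	-6.1882690134406	-10.9955245736991
3.8	3.8642567206886	-10.5626239261667
4	-1.67500898250083	-9.68808482354952
4.2	4.107032549786	-0.129968632080129
4.4	-0.338475678300067	-5.73537329152481
4.6	4.94861223291164	-12.5398298187913
4.8	6.70943453748739	-15.4298595534778
5	2.7794367857442	-13.9640252651001
5.2	3.95156038440704	-12.3165648876156
5.4	0.852447658688472	-11.8447267271777
5.6	-6.18006163312354	-2.40624268101502
5.8	7.19327334100301	-11.2437160662339
6	-0.703923148994651	-7.06171039588633
6.2	0.574728544782646	-7.16040107611869
6.4	-5.9710774129457	-8.99770473235191
6.6	-6.81727112840823	-5.37540338070596
6.8	10.5012513831616	-10.3281051089505
7	-2.67817694166119	-5.98410380419126
7.2	13.3034436762947	-15.4629248036241
7.4	-1.37586931470917	-28.0780445918894
7.6	-6.17765821925758	-28.8870099613431
7.8	-4.27003685196087	-30.6886701381701
8	-2.70239447313057	-20.7757730278572
8.2	-1.16040321710018	-22.3906419300211
8.4	2.4647700067869	-23.1146450040705
8.6	-7.34479815181041	-27.4015045902445
8.8	0.15396666985471	-27.4152571617654
9	1.78335697081881	-22.4885321070913
9.2	1.5402685462942	-36.5118094879464
9.4	-4.18452942241365	-37.7951200864089
9.6	1.93034371878252	-34.9974058750873
9.8	-2.9974912299189	-44.5605682332405
10	-2.07911518087748	-45.6462512713473
10.2	0.514564495379156	-39.9383810939066
10.4	0.532086784151872	-56.5945103325654
10.6	-8.23219944791569	-55.6650031006819
10.8	-6.02280314695476	-55.6658603501584
11	5.83273300989859	-62.7244223129789
11.2	5.70767711692846	-54.3304183689091
11.4	-5.11517549230551	-66.9799841799621
11.6	0.869413309179424	-70.7421252655397
11.8	6.40162537142889	-81.4810281326526
12	1.53665800353255	0.435978586198066
12.2	-4.19051336701255	0.886869534144375
12.4	-2.6342188510157	-4.60427605164646
12.6	3.99238381958775	-3.54782433501229
12.8	-7.21201239641325	-1.26814888031028
13	6.9596430538976	-2.08057418994487
13.2	12.1621501699494	1.11364581320526
13.4	-3.17246684849161	0.530519878887688
13.6	4.18189090992632	5.58102052270273
13.8	-0.42408456626635	-0.44805484225719
14	5.42254027054918	3.06833178799308
14.2	-14.2889524684773	-10.0343228735934
14.4	-10.8926788507032	-2.99077899519684
14.6	2.87584155652251	-2.79520568852183
14.8	0.0132123479370216	2.46434148481857
15	-0.185279671973056	-5.77053007705185
15.2	0.41555423801028	-1.74369136355116
15.4	-4.6202361353637	-0.0882671269762547
15.6	1.53151818747718	9.46500883974869
15.8	2.67095864165832	-9.0308647032107
16	-7.06569807528744	-6.3741239695556
16.2	-5.14302615132502	-12.2934794589627
16.4	6.41017916126045	2.68914527620483
16.6	2.5940926270833	6.98086012090235
16.8	-0.545427683602109	-5.74669064094178
17	-9.29315629520413	-3.30731279466915
17.2	-11.5433701424101	5.49550038402255
17.4	1.31432045947212	8.33495358294646
17.6	-6.11434526756645	2.18231391148055
17.8	-9.45138095434989	3.88454964984884
18	-3.88900484756473	5.51794953214847
18.2	-0.0438640310446357	0.746913097257997
18.4	-3.01851927775338	-6.02682255510124
18.6	2.88923592844259	-0.919706838119981
18.8	-3.54475280173807	-2.77490518597368
19	7.29501080037004	-10.3684168107967
19.2	6.31222297543328	-7.02949145509307
19.4	3.26405477051917	1.45990770394431
19.6	9.40879865410394	4.28821305723475
19.8	-0.665692599991408	9.8327361283051
20	5.30934604491272	-6.07310824978635
20.2	-3.99125302607324	-0.612270440582287
20.4	11.9406715009157	6.58100879448889
20.6	2.64259361951465	-4.26849824824953
20.8	8.22812088578431	-5.81668613770241
21	-2.27276807563381	0.585075156839786
21.2	6.56965764512491	4.19893707889654
21.4	-0.855269290617806	3.01885583227151
21.6	8.2236077777733	-0.209759182916753
21.8	2.18107039950153	-6.78456481076719
22	11.3786839120277	-4.4249781476205
22.2	1.40739717694727	-9.40056085188283
22.4	-6.15473152427986	2.79566879571836
22.6	2.47099311083395	-1.27755416304424
22.8	-5.68249825899498	6.10040676240917
23	-4.84800712175301	-4.60846671600648
23.2	-8.94663186323866	-6.54566780688673
23.4	-7.53514136145873	2.23245548614028
23.6	5.92501590791148	13.5165658781991
23.8	-0.0776165353989929	4.5395844175963
24	-3.26903165786082	-2.13331984203717
24.2	1.38127682881253	-2.67806037381225
24.4	5.53472176627443	8.82716565711653
24.6	-3.04053725532752	1.06125834083953
24.8	2.7626267707539	4.82040027158725
25	2.7472374832076	4.37283755033144
25.2	-8.97840023271098	2.38305637386728
25.4	-1.70736267212992	-2.5663171760438
25.6	-2.76744172363344	-6.24911106857078
25.8	-6.6210998777711	5.53605033426887
26	0.520306698308325	3.07067696369598
26.2	1.23395778350318	4.66282690332882
26.4	-2.31685862132438	-7.36551007751295
26.6	-3.82653551133367	-4.52505024333823
26.8	-3.8617878705026	-3.34822244229712
27	-0.69602073376975	-4.14602978814337
27.2	6.14011053256806	-2.55282972459122
27.4	1.64248197923173	3.16073611710364
27.6	1.48121193719186	-4.70294063076775
27.8	-2.90118945353729	0.885035911924701
28	11.111929203423	3.92391656916463
28.2	1.73506045937341	7.15331261050975
28.4	0.724662950702986	0.730380667663024
28.6	-4.05826963677702	14.6873122844172
28.8	6.64439288144634	-3.70211473568433
29	6.43301330534325	2.25507770140148
29.2	7.45557574167689	5.2544865379127
29.4	4.87688645223717	-2.49318760076644
29.6	-2.31491988822269	-4.11131628067493
29.8	3.71433096323238	-2.31309880115582
30	5.04196293676066	0.833313261557752
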