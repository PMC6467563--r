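x_um,y_um
566.0714285714287,0
565.9233421885498,11.18322020305249
565.479741663699,22.3576390197742
564.7425922790648,33.51456633321925
563.715134398048,44.6455322368291
562.4018314674915,55.74239136541738
560.8082985333875,66.79742042708212
558.9412125534633,77.80340688358909
556.8082061156553,88.75372690471528
554.4177464673432,99.6424109378431
551.7790020208922,110.46419548353056
548.901698721729,121.21455994595433
545.7959688418499,131.8897477285785
542.4721948910695,142.486771064221
538.9408514181788,153.00339939860842
535.212347503065,163.4381314810376
531.2968727183152,173.79015164831034
527.2042492653968,184.05927111211278
522.9437928676471,194.24585536907117
518.5241848323993,204.35073914070293
513.9533574808938,214.37513051167127
509.23839489123407,224.3205061639309
504.38545061138876,234.18849979691277
499.3996836815503,243.9807859759486
494.2852139640407,253.6989617595492
489.0450974208455,263.34442851865634
483.6813216104709,272.91827637618655
478.19482130407545,282.4211736626057
472.58551375267433,291.8532637033597
466.85235277952677,301.21407112811136
460.9934005312407,310.5024197221612
455.0059154039877,319.7163636302676
448.886454373365,328.853133476255
442.6309877031588,337.90909868292346
436.2350237941754,346.87974697112406
429.6937417632771,355.7596816902343
423.00212921783543,364.54263729088075
416.1551226141444,373.2215129011332
409.14774756117225,381.7884236162403
401.975256453661,390.23476876605326
394.63326089036764,398.5513160902587
387.11785645259494,406.7283004358927
379.42573758261267,414.75553530047245
371.5543005077938,422.62253528315244
363.50173240017216,430.3186472807179
355.26708523785743,437.83318807944164
346.8503331388968,445.1555858515822
338.25241226381644,452.27552296949983
329.4752427238916,459.1830775030335
320.5217322815951,465.8688607680541
311.3957619809189,472.32414834613803
302.10215419161614,478.5410020963379
292.64662388623367,484.5123808283516
283.0357142857143,490.2322374994056
273.27671830231606,495.6956010314041
263.37758747208284,500.8986411161121
253.3468302981458,505.8387146793573
243.19340211645294,510.51439300488323
232.9265887435999,514.9254688684508
222.55588626957106,519.072943396582
212.09087941456647,522.9589927351714
201.54112087779774,526.5869149841569
190.91601406717112,529.961058218561
180.2247015130983,533.086730766683
169.47596113911632,535.9700952464268
158.6781123892551,538.6180481644712
147.83893400070193,541.0380871544796
136.96559496451786,543.2381681646617
126.06459994189267,545.2265550972779
115.14175010417081,547.0116645494436
104.20212004756155,548.6019084029936
93.25005110436993,550.0055370593054
82.28916103822395,551.230486111827
71.32236977773505,552.2842291945948
60.35194051786913,553.1736396401859
49.37953520740113,553.9048634271803
38.40628315030954,554.4832056981098
27.432861184513904,554.9130328876606
16.459583668171092,555.197692222016
5.4865003063954845,555.3394500387923
-5.486500306395416,555.3394500387923
-16.45958366817115,555.197692222016
-27.432861184513833,554.9130328876606
-38.4062831503096,554.4832056981098
-49.37953520740106,553.9048634271803
-60.35194051786918,553.1736396401859
-71.32236977773509,552.2842291945948
-82.28916103822388,551.2304861118271
-93.25005110436999,550.0055370593054
-104.2021200475615,548.6019084029936
-115.14175010417088,547.0116645494436
-126.06459994189274,545.2265550972779
-136.96559496451778,543.2381681646617
-147.83893400070195,541.0380871544796
-158.678112389255,538.6180481644712
-169.47596113911638,535.9700952464268
-180.22470151309835,533.086730766683
-190.91601406717103,529.961058218561
-201.5411208777978,526.5869149841569
-212.0908794145664,522.9589927351714
-222.55588626957112,519.072943396582
-232.92658874359998,514.9254688684508
-243.19340211645297,510.5143930048831
-253.34683029814585,505.8387146793573
-263.3775874720828,500.8986411161121
-273.276718302316,495.6956010314041
-283.03571428571445,490.2322374994054
-292.6466238862338,484.5123808283516
-302.1021541916162,478.5410020963379
-311.3957619809189,472.32414834613803
-320.52173228159506,465.8688607680541
-329.47524272389165,459.1830775030334
-338.25241226381655,452.27552296949983
-346.85033313889693,445.15558585158226
-355.26708523785743,437.83318807944164
-363.5017324001721,430.318647280718
-371.55430050779387,422.6225352831524
-379.4257375826127,414.75553530047245
-387.11785645259494,406.7283004358927
-394.6332608903676,398.55131609025875
-401.97525645366096,390.2347687660533
-409.1477475611723,381.7884236162402
-416.15512261414443,373.2215129011332
-423.00212921783543,364.54263729088075
-429.69374176327705,355.7596816902343
-436.23502379417533,346.8797469711242
-442.6309877031589,337.90909868292334
-448.886454373365,328.8531334762549
-455.0059154039877,319.7163636302676
-460.9934005312407,310.5024197221613
-466.8523527795267,301.2140711281114
-472.5855137526744,291.8532637033596
-478.19482130407545,282.42117366260567
-483.6813216104709,272.91827637618655
-489.0450974208454,263.3444285186564
-494.2852139640406,253.69896175954932
-499.39968368155036,243.98078597594852
-504.3854506113888,234.18849979691274
-509.23839489123407,224.3205061639309
-513.9533574808938,214.37513051167133
-518.5241848323993,204.350739140703
-522.9437928676471,194.2458553690711
-527.2042492653969,184.05927111211275
-531.2968727183152,173.79015164831034
-535.212347503065,163.43813148103766
-538.9408514181788,153.0033993986085
-542.4721948910695,142.4867710642209
-545.7959688418499,131.88974772857844
-548.901698721729,121.21455994595433
-551.7790020208921,110.46419548353063
-554.4177464673432,99.64241093784321
-556.8082061156553,88.7537269047152
-558.9412125534634,77.80340688358906
-560.8082985333875,66.79742042708213
-562.4018314674915,55.742391365417454
-563.715134398048,44.64553223682922
-564.7425922790648,33.51456633321917
-565.479741663699,22.35763901977417
-565.9233421885498,11.183220203052509
-566.0714285714287,6.932375630887697e-14
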