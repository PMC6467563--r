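x_um,y_um
553.5714285714287,0
553.3380629105111,10.934522298246282
552.6400597409006,21.849990465090222
551.4836652444538,32.727717252445125
549.8791728334156,43.549741419147864
547.8407500227528,54.299171490975596
545.3862004266022,64.96050686178593
542.5366651567233,75.5199293958245
539.3162689861838,85.96555928438913
535.7517176276817,96.2876696293797
531.8718533447939,106.47885505770374
527.7071768500116,116.53415059774508
523.2893440322853,126.45109805395005
518.6506464881556,136.22975817831107
513.8234850967107,145.87266803725012
508.83984597485306,155.38474408749082
503.73078807423576,164.77313258299264
498.52595143643066,174.04701001503201
493.25309471332866,183.21733731770553
487.9376699933915,192.2965725310787
482.6024422620726,201.2983474848282
477.2671599800889,210.23711482914
471.9482823023128,219.1277723814917
466.6587674010612,227.9852722647701
461.4079252204724,236.82422267354656
456.20133679492506,245.6584903136701
451.0408410364746,254.50081161098805
445.92458865711063,263.36242067639165
440.8471616644342,272.2527017479906
435.7997556770302,281.1788734116264
430.77042117053327,290.14571133566744
425.7443587082223,299.1553155554869
420.7042622504258,308.20692752023876
415.63070379272494,317.2968011849536
410.50255186928683,326.4181314121257
405.29741588754,335.5610418581817
399.99210784395774,344.7126333822403
394.5631127151309,353.8570928491472
388.98705872773746,362.9758610282383
383.2411787864283,372.04785713618134
377.3037545779061,381.04975645880955
371.1545352673004,389.9563164346789
364.77512325109456,398.74074561260494
358.14932011824953,407.3751090256509
351.263426784087,415.8307627720298
344.10649268391,424.0788099740821
336.67050992715286,432.09056981230185
328.950549398321,439.8380510120159
320.944836927009,447.2944210025364
312.65476881393323,454.434461976138
304.0848671707186,461.2350052476277
295.24267668566614,467.6753356520246
286.13860554378425,473.7375582122514
276.7857142857143,479.4069199521001
267.19945736672685,484.67208051049766
257.3973830552344,489.52532611711484
247.39879807373515,493.96272250007286
237.22440401948242,497.9842033952858
226.8959130957437,501.593592493512
216.43565102828111,504.7985578738018
205.86615522957052,507.61049920812644
195.20977630227364,510.04436925847125
184.4882908435947,512.11843240140945
173.72253322654421,513.8539640833546
162.93205359891704,515.27489621035
152.13480876498497,516.407414488629
141.34689191024952,517.2795146371207
130.58230631028246,517.9205251734314
119.85278724711559,518.3606051157291
109.16767535910485,518.6302254321398
98.53384359247305,518.7596433972724
87.95567882578868,518.7783791758872
77.43511812410476,518.7147039432044
66.97173846934767,518.5951486697818
56.56289772966308,518.4440423493787
46.20392359409056,518.2830879369785
35.888346230527915,518.1309836004375
25.60816954344227,518.003096085173
15.354175130490743,517.9111920616607
5.116252379363997,517.8632322873798
-5.116252379363933,517.8632322873798
-15.354175130490798,517.9111920616608
-25.608169543442205,518.003096085173
-35.888346230527965,518.1309836004375
-46.2039235940905,518.2830879369785
-56.56289772966313,518.4440423493787
-66.97173846934771,518.5951486697818
-77.4351181241047,518.7147039432045
-87.95567882578874,518.7783791758872
-98.53384359247299,518.7596433972724
-109.1676753591049,518.6302254321398
-119.85278724711564,518.3606051157291
-130.5823063102824,517.9205251734314
-141.34689191024955,517.2795146371207
-152.1348087649849,516.407414488629
-162.9320535989171,515.27489621035
-173.72253322654427,513.8539640833546
-184.48829084359463,512.11843240140945
-195.2097763022737,510.04436925847125
-205.86615522957044,507.6104992081264
-216.43565102828117,504.7985578738018
-226.89591309574377,501.593592493512
-237.22440401948245,497.98420339528576
-247.3987980737352,493.96272250007286
-257.39738305523434,489.52532611711484
-267.1994573667268,484.67208051049766
-276.78571428571445,479.40691995209994
-286.1386055437843,473.7375582122514
-295.2426766856662,467.6753356520246
-304.0848671707186,461.2350052476277
-312.6547688139332,454.434461976138
-320.9448369270091,447.29442100253635
-328.9505493983211,439.8380510120159
-336.670509927153,432.09056981230196
-344.10649268391,424.0788099740821
-351.26342678408696,415.83076277202986
-358.1493201182496,407.37510902565083
-364.77512325109467,398.74074561260494
-371.1545352673004,389.9563164346789
-377.30375457790603,381.0497564588096
-383.24117878642824,372.0478571361814
-388.9870587277375,362.97586102823817
-394.56311271513096,353.8570928491472
-399.99210784395774,344.7126333822403
-405.29741588753996,335.5610418581817
-410.5025518692868,326.4181314121258
-415.630703792725,317.2968011849535
-420.7042622504258,308.2069275202387
-425.7443587082223,299.1553155554869
-430.77042117053327,290.1457113356675
-435.79975567703013,281.17887341162645
-440.84716166443434,272.2527017479905
-445.92458865711063,263.3624206763916
-451.0408410364746,254.50081161098805
-456.201336794925,245.65849031367011
-461.40792522047235,236.82422267354664
-466.65876740106125,227.98527226477
-471.94828230231286,219.12777238149167
-477.2671599800889,210.23711482914
-482.6024422620726,201.29834748482827
-487.9376699933915,192.2965725310788
-493.25309471332866,183.21733731770547
-498.5259514364307,174.047010015032
-503.73078807423576,164.77313258299264
-508.83984597485306,155.38474408749087
-513.8234850967107,145.8726680372502
-518.6506464881556,136.229758178311
-523.2893440322853,126.45109805395
-527.7071768500116,116.53415059774508
-531.8718533447937,106.47885505770383
-535.7517176276817,96.2876696293798
-539.3162689861838,85.96555928438903
-542.5366651567234,75.51992939582448
-545.3862004266022,64.96050686178594
-547.8407500227528,54.29917149097566
-549.8791728334156,43.54974141914798
-551.4836652444538,32.72771725244504
-552.6400597409006,21.84999046509019
-553.3380629105111,10.9345222982463
-553.5714285714287,6.779294780994278e-14
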