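species,yield_class,age,volume_m3_ha
sitka_spruce,16,0,0
sitka_spruce,16,1,0.28198465477906315
sitka_spruce,16,2,1.5274476184884684
sitka_spruce,16,3,4.031541566863376
sitka_spruce,16,4,7.928762797537321
sitka_spruce,16,5,13.273291303026015
sitka_spruce,16,6,20.06968581009693
sitka_spruce,16,7,28.28961069826187
sitka_spruce,16,8,37.8823370997974
sitka_spruce,16,9,48.781864743554394
sitka_spruce,16,10,60.91198297254026
sitka_spruce,16,11,74.18997484197558
sitka_spruce,16,12,88.52937877951366
sitka_spruce,16,13,103.84206999693326
sitka_spruce,16,14,120.03983677590077
sitka_spruce,16,15,137.03557364767198
sitka_spruce,16,16,154.74417937564567
sitka_spruce,16,17,173.08322479025728
sitka_spruce,16,18,191.97343965942957
sitka_spruce,16,19,211.33905643720422
sitka_spruce,16,20,231.10804042426219
sitka_spruce,16,21,251.21222965732912
sitka_spruce,16,22,271.58740310940124
sitka_spruce,16,23,292.1732921208933
sitka_spruce,16,24,312.91354711290086
sitka_spruce,16,25,333.7556693609737
sitka_spruce,16,26,354.65091579006236
sitka_spruce,16,27,375.554183285736
sitka_spruce,16,28,396.42387782694533
sitka_spruce,16,29,417.22177277406416
sitka_spruce,16,30,437.9128598487309
sitka_spruce,16,31,458.4651956852511
sitka_spruce,16,32,478.84974629049475
sitka_spruce,16,33,499.0402312994266
sitka_spruce,16,34,519.0129695400136
sitka_spruce,16,35,538.7467271108898
sitka_spruce,16,36,558.2225689170355
sitka_spruce,16,37,577.4237143940553
sitka_spruce,16,38,596.3353979732192
sitka_spruce,16,39,614.944734691326
sitka_spruce,16,40,633.2405912268
sitka_spruce,16,41,651.2134625421043
sitka_spruce,16,42,668.8553542292108
sitka_spruce,16,43,686.1596705866353
sitka_spruce,16,44,703.1211084010439
sitka_spruce,16,45,719.7355563616659
sitka_spruce,16,46,736
sitka_spruce,16,47,751.9124320191663
sitka_spruce,16,48,767.4717678554863
sitka_spruce,16,49,782.6777662984877
sitka_spruce,16,50,797.5309549836076
sitka_spruce,16,51,812.0325605637048
sitka_spruce,16,52,826.1844433604385
sitka_spruce,16,53,839.9890362940836
sitka_spruce,16,54,853.4492878900174
sitka_spruce,16,55,866.5686091614758
sitka_spruce,16,56,879.3508241709771
sitka_spruce,16,57,891.8001240767206
sitka_spruce,16,58,903.9210244750783
sitka_spruce,16,59,915.7183258557864
sitka_spruce,16,60,927.1970769924764
sitka_spruce,16,61,938.3625410975625
sitka_spruce,16,62,949.2201645771814
sitka_spruce,16,63,959.7755482286823
sitka_spruce,16,64,970.0344207300701
sitka_spruce,16,65,980.0026142776989
sitka_spruce,16,66,989.6860422353814
sitka_spruce,16,67,999.0906786648239
sitka_spruce,16,68,1008.2225396139456
sitka_spruce,16,69,1017.08766604609
sitka_spruce,16,70,1025.692108299446
sitka_spruce,16,71,1034.0419119720577
sitka_spruce,16,72,1042.1431051336929
sitka_spruce,16,73,1050.001686771476
sitka_spruce,16,74,1057.623616381622
sitka_spruce,16,75,1065.0148046247896
sitka_spruce,16,76,1072.1811049675377
sitka_spruce,16,77,1079.1283062370892
sitka_spruce,16,78,1085.8621260211162
sitka_spruce,16,79,1092.3882048485323
sitka_spruce,16,80,1098.7121010913343
sitka_spruce,16,81,1104.8392865313965
sitka_spruce,16,82,1110.7751425397432
sitka_spruce,16,83,1116.5249568192864
sitka_spruce,16,84,1122.0939206652536
sitka_spruce,16,85,1127.4871267006085
sitka_spruce,16,86,1132.7095670466517
sitka_spruce,16,87,1137.7661318917167
sitka_spruce,16,88,1142.6616084234342
sitka_spruce,16,89,1147.4006800924494
sitka_spruce,16,90,1151.9879261777407
sitka_spruce,16,91,1156.427821625804
sitka_spruce,16,92,1160.724737137972
sitka_spruce,16,93,1164.8829394819936
sitka_spruce,16,94,1168.9065920057503
sitka_spruce,16,95,1172.7997553326338
sitka_spruce,16,96,1176.566388219621
sitka_spruce,16,97,1180.2103485605371
sitka_spruce,16,98,1183.7353945183206
sitka_spruce,16,99,1187.1451857713566
sitka_spruce,16,100,1190.4432848601166
sitka_spruce,16,101,1193.6331586214242
sitka_spruce,16,102,1196.7181796986854
sitka_spruce,16,103,1199.7016281173624
sitka_spruce,16,104,1202.586692915853
sitka_spruce,16,105,1205.3764738227562
sitka_spruce,16,106,1208.0739829722613
sitka_spruce,16,107,1210.6821466501171
sitka_spruce,16,108,1213.2038070632786
sitka_spruce,16,109,1215.6417241269523
sitka_spruce,16,110,1217.9985772633272
sitka_spruce,16,111,1220.2769672067907
sitka_spruce,16,112,1222.4794178109348
sitka_spruce,16,113,1224.6083778530908
sitka_spruce,16,114,1226.6662228325586
sitka_spruce,16,115,1228.655256759081
sitka_spruce,16,116,1230.5777139284637
sitka_spruce,16,117,1232.4357606825795
sitka_spruce,16,118,1234.2314971512933
sitka_spruce,16,119,1235.9669589741247
sitka_spruce,16,120,1237.644118999727
sitka_spruce,16,121,1239.2648889614927
sitka_spruce,16,122,1240.83112112782
sitka_spruce,16,123,1242.3446099257696
sitka_spruce,16,124,1243.8070935370297
sitka_spruce,16,125,1245.2202554652733
sitka_spruce,16,126,1246.5857260741452
sitka_spruce,16,127,1247.9050840952602
sitka_spruce,16,128,1249.1798581057183
sitka_spruce,16,129,1250.411527974766
sitka_spruce,16,130,1251.6015262793323
sitka_spruce,16,131,1252.751239688273
sitka_spruce,16,132,1253.8620103152368
sitka_spruce,16,133,1254.9351370401507
sitka_spruce,16,134,1255.9718767993963
sitka_spruce,16,135,1256.973445844806
sitka_spruce,16,136,1257.9410209716739
sitka_spruce,16,137,1258.8757407160213
sitka_spruce,16,138,1259.7787065214086
sitka_spruce,16,139,1260.650983875622
sitka_spruce,16,140,1261.4936034176055
sitka_spruce,16,141,1262.3075620150305
sitka_spruce,16,142,1263.0938238129354
sitka_spruce,16,143,1263.8533212538835
sitka_spruce,16,144,1264.5869560701105
sitka_spruce,16,145,1265.2956002481515
sitka_spruce,16,146,1265.9800969664507
sitka_spruce,16,147,1266.64126150647
sitka_spruce,16,148,1267.2798821378253
sitka_spruce,16,149,1267.8967209779769
sitka_spruce,16,150,1268.4925148270231
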