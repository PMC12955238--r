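"wavelength_nm","sL","sM","sS"
380,5.49026815868721e-05,2.88596533275163e-05,0.00363972891073353
390,0.000165921618046912,9.03756013530289e-05,0.01131419607135
400,0.000534464710189005,0.000305099306594989,0.038287690944693
410,0.00153884967755153,0.000981540042245212,0.117035624199401
420,0.00452682901159141,0.00353734167453603,0.36431147050691
430,0.0100502820940716,0.0118622280749326,0.781892771893393
440,0.0147599759584025,0.0262108474714899,0.985864308649012
450,0.0185828203739083,0.0463270575052397,1
460,0.0243982069312753,0.0757200913622007,0.941927984154483
470,0.0392164872737644,0.113640594903647,0.726614036374717
480,0.0722426104386222,0.167188935691069,0.458746917516407
490,0.124633112091829,0.241512817454904,0.262500634836438
500,0.212311447375312,0.365172320181815,0.153489343212329
510,0.353140140771134,0.556895357450802,0.0892721106477589
520,0.530834186863566,0.769144003579689,0.0441564011263409
530,0.684962766937306,0.912629157682084,0.023790848197911
540,0.803933878377468,0.986041910624385,0.0114552708353319
550,0.892675830766554,1,0.0049376167393672
560,0.958736638704556,0.965520152374494,0.00220076631811795
570,0.996201979762832,0.882525962103611,0.00118502801744813
580,1,0.759641451262322,0.000931093442280671
590,0.963462657771337,0.612149282249605,0.000620728961520447
600,0.887344650466682,0.466193279682397,0.000451439244742144
610,0.770883979996233,0.338390021150188,0.000191861679015411
620,0.622637282637858,0.236058831262809,0.000107216820626259
630,0.452673793843869,0.153932931475679,2.8214952796384e-05
640,0.308583273554334,0.096607508428162,1.12859811185536e-05
650,0.192606276600033,0.0570131651751532,0
660,0.111139526306533,0.0318040567078867,0
670,0.0586674365969388,0.0164933188378088,0
680,0.0313051119158815,0.00868987494433099,0
690,0.0151645088915111,0.00417264762278443,0
700,0.00758376060330813,0.00208111291158163,0
710,0.00386572395615949,0.00106090668113418,0
720,0.00193557253886639,0.000531247112685915,0
730,0.000961393713096467,0.000263806944492887,0
740,0.00046054775277461,0.000126224569083811,0
750,0.000221734707019984,6.09441067485476e-05,0
760,0.000110867353509992,3.04720533742738e-05,0
770,5.54336767549959e-05,1.52360266871369e-05,0
780,2.79205818811995e-05,7.51144406201134e-06,0
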