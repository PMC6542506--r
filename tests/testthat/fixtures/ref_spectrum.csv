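# K: 1
# source: frozen-reference
frequency_hz,power
2,0.3115070170144561
2.25,0.31846528310144778
2.5,0.32649823530010991
2.75,0.33570023098591495
3,0.34618034010387655
3.25,0.35806373993213142
3.5,0.37149314926913735
3.75,0.38663021112989804
4,0.40365667996807203
4.25,0.42277519293581539
4.5,0.44420929666561509
4.75,0.46820225206496324
5,0.49501394001599491
5.25,0.52491493369759679
5.5,0.55817649011118109
5.75,0.59505486540083619
6,0.63576803454124398
6.25,0.68046271964649718
6.5,0.72916982534068064
6.75,0.78174729591993941
7,0.83781152225184319
7.25,0.8966622338500444
7.5,0.95721155191703444
7.75,1.0179350071904472
8,1.0768688327592251
8.25,1.1316798522698557
8.5,1.1798267956992798
8.75,1.2188114600671534
9,1.2464871577511156
9.25,1.2613613193079085
9.5,1.2628155071153542
9.75,1.2511816968807059
10,1.2276558045873971
10.25,1.1940792974188794
10.5,1.1526540051020835
10.75,1.1056611679557924
11,1.0552371084128189
11.25,1.0032288769480124
11.5,0.95112767412215704
11.75,0.90006279437568526
12,0.85083430431938567
12.25,0.80396505647220318
12.5,0.75975795868276652
12.75,0.71834991130016779
13,0.67975817432910091
13.25,0.64391783461103991
13.5,0.61071071405907107
13.75,0.57998685347024859
14,0.551579956952433
14.25,0.52531813816442818
14.5,0.50103113245396735
14.75,0.47855492190527482
15,0.45773451124487546
15.25,0.43842541211472003
15.5,0.4204942470144068
15.75,0.40381877049926829
16,0.38828751927667166
16.25,0.37379923925435715
16.5,0.36026219132521153
16.75,0.34759340447007936
17,0.33571792122796285
17.25,0.32456806410364064
17.5,0.31408274008737591
17.75,0.30420679269440098
18,0.29489040573127889
18.25,0.28608855959491408
18.5,0.27776053875847634
18.75,0.26986948780589676
19,0.26238201266675742
19.25,0.25526782338240583
19.5,0.24849941466676742
19.75,0.2420517806181483
20,0.2359021601271831
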