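"time_ms","amplitude_mv"
0,0
0.1,0
0.2,0
0.3,0
0.4,0
0.5,0
0.6,0
0.7,0
0.8,0
0.9,0
1,0
1.1,0
1.2,0
1.3,0
1.4,0
1.5,0
1.6,0
1.7,0
1.8,0
1.9,0
2,0
2.1,0
2.2,0
2.3,0
2.4,0
2.5,0
2.6,0
2.7,0
2.8,0
2.9,0
3,0
3.1,0
3.2,0
3.3,0
3.4,0
3.5,-0.0136627924244217
3.6,-0.0233443851055935
3.7,-0.0384218201499682
3.8,-0.0609727243390274
3.9,-0.0933513196946741
4,-0.137945045730281
4.1,-0.196791486751676
4.2,-0.271077886633988
4.3,-0.360589599177421
4.4,-0.463217083849388
4.5,-0.574657903818907
4.6,-0.688444946626142
4.7,-0.796385576394593
4.8,-0.889411908862831
4.9,-0.958737972158141
5,-0.997124670348014
5.1,-1
5.2,-0.966192174781216
5.3,-0.898110286674449
5.4,-0.801331757838262
5.5,-0.683692392722149
5.6,-0.554083371522075
5.7,-0.421209974181114
5.8,-0.292549068263172
5.9,-0.173668296813176
6,-0.0679671024628878
6.1,0.0231995550594508
6.2,0.100124085230716
6.3,0.164214054431479
6.4,0.217453457342536
6.5,0.261950317229533
6.6,0.29961807413201
6.7,0.331997262890861
6.8,0.360195793429699
6.9,0.384912813961767
7,0.406510130982177
7.1,0.425101780486755
7.2,0.440641897462055
7.3,0.453000107628752
7.4,0.462020504592719
7.5,0.467564480365296
7.6,0.469539674294945
7.7,0.467917829800935
7.8,0.462744098031052
7.9,0.454139805708177
8,0.442300197051248
8.1,0.42748828380662
8.2,0.41002570700689
8.3,0.390281395171079
8.4,0.368658750265819
8.5,0.345582064821138
8.6,0.321482843292464
8.7,0.296786652419515
8.8,0.271901053006307
8.9,0.247205070109523
9,0.223040545253104
9.1,0.199705590500372
9.2,0.177450238384134
9.3,0.156474261952039
9.4,0.136927032621811
9.5,0.118909195671881
9.6,0.1024758776429
9.7,0.0876410983375399
9.8,0.0743830422335835
9.9,0.0626498480781803
10,0.0523655980303074
10.1,0.0434362249142783
10.2,0.0357551034528502
10.3,0.0292081442484814
10.4,0.0236782635800952
10.5,0.0190491541729213
10.6,0.0152083291368169
10.7,0.0120494512566823
10.8,0.00947399160529988
10.9,0.00739228465753782
11,0.00572406199390327
11.1,0.00439855407457277
11.2,0.00335425057025793
11.3,0.0025384056704407
11.4,0.00190636702080027
11.5,0.00142079677784014
11.6,0.00105084187540475
11.7,0.000771298946644856
11.8,0.000561808189694473
11.9,0.000406100340325121
12,0.000291312151825532
12.1,0
12.2,0
12.3,0
12.4,0
12.5,0
12.6,0
12.7,0
12.8,0
12.9,0
13,0
13.1,0
13.2,0
13.3,0
13.4,0
13.5,0
13.6,0
13.7,0
13.8,0
13.9,0
14,0
14.1,0
14.2,0
14.3,0
14.4,0
14.5,0
14.6,0
14.7,0
14.8,0
14.9,0
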