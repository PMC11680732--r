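offset_ppm,z
-5,0.383149824263841
-4.8,0.368746143057355
-4.6,0.35269957180483
-4.4,0.335214348883812
-4.2,0.316897746455496
-4,0.298878250304089
-3.8,0.282703038561158
-3.6,0.26985524135228
-3.4,0.261014331076111
-3.2,0.255559338373481
-3,0.251756355297961
-2.8,0.247486503736886
-2.6,0.24094863300724
-2.4,0.230968459286961
-2.2,0.216967745648021
-2,0.198829588622307
-1.8,0.176849993240445
-1.6,0.151809779579009
-1.4,0.124996345703475
-1.2,0.0980160507231647
-1,0.0725542463427487
-0.8,0.0495114420282083
-0.6,0.0294090897316851
-0.399999999999999,0.0135333077145979
-0.199999999999999,0.0034280004543078
0,1.37833626450683e-05
0.2,0.00303723897709371
0.4,0.0111713239907317
0.600000000000001,0.0225700640359285
0.800000000000001,0.03586485671096
1,0.0506825570840562
1.2,0.0672173253489227
1.4,0.0846293779437731
1.6,0.100335862669945
1.8,0.112746518916183
2,0.126210707243689
2.2,0.146952806798116
2.4,0.170755688600615
2.6,0.18928185859935
2.8,0.200283017002888
3,0.206475844511877
3.2,0.211689972076458
3.4,0.219015916937149
3.6,0.231181543264602
3.8,0.249440154655728
4,0.272449988425335
4.2,0.297340469988145
4.4,0.321504516684788
4.6,0.343448965388619
4.8,0.362678555087262
5,0.379273863681721
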