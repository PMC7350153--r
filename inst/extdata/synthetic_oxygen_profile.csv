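depth_um,o2
0,0.576085852743747
5,0.475585419502684
10,0.455795312176872
15,0.432574756332596
20,0.393524409518162
25,0.367085882775758
30,0.375062610293787
35,0.33280202627979
40,0.314206600180598
45,0.331934169715385
50,0.273221928213819
55,0.299328588933123
60,0.270494695592053
65,0.21217556032366
70,0.225399582228045
75,0.179564258038217
80,0.136011495759282
85,0.132356725737594
90,0.123955211265951
95,0.130288623730197
100,0.114710953228396
105,0.100320597376129
110,0.101526784503371
115,0.0377240302247195
120,0.0818860646347431
125,0.0519045635006708
130,0.0558872300104515
135,0.046100424622672
140,0.00880206452903899
145,0.0178790136131293
150,0.00162060249643859
155,0.0297043471407365
160,0.0144405410025365
165,0.00810533744970431
170,0
175,0
180,0.0246809710256221
185,0
190,0.000296449986437877
195,0.00902588491784562
200,0.0268959681988851
205,0
210,0
215,0
220,0
225,0
230,0.0330177340749134
235,0.0194663422716577
240,0.0117215238082415
245,0.0308935030493032
250,0.0101290048280859
255,0.0189479466968572
260,0.0308177619649821
265,0.0626921653722277
270,0.0488380949058563
275,0.0505725857446629
280,0.0169864687349954
285,0.0629291146283975
290,0.0689537303419853
295,0.0575731126516631
300,0.0879190183646076
305,0.101291124866301
310,0.121605307820225
315,0.138368842461248
320,0.145118385630704
325,0.176322999317726
330,0.185859100572952
335,0.210828040535613
340,0.231204174897788
345,0.239188575194401
350,0.253971693430393
355,0.247970965215583
360,0.276178963152905
365,0.294191577406529
370,0.302737432371537
375,0.333985034185783
380,0.368668124305482
385,0.402218615124678
390,0.44002078697291
395,0.518598694178131
400,0.506851707002946
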