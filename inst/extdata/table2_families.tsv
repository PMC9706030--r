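section	family_label	description	gene_count	read_count
LMEs	AA2	Manganese peroxidase; versatile peroxidase; lignin peroxidase; peroxidase	1	1240
LMEs	AA4	Vanillyl-alcohol oxidase	15	56066
LMEs	AA6	1,4-benzoquinone reductase	39	66334
LMEs	AA7	Glucooligosaccharide oxidase; chitooligosaccharide oxidase	2	1608
Lignocellulose-binding modules	CBM3	Cellulose binding	7	28046
Lignocellulose-binding modules	CBM4	Cellulose, xylan, beta-1,3-glucan, beta-1,3-1,4-glucan, beta-1,6-glucan binding	3	21588
Lignocellulose-binding modules	CBM6	Cellulose and beta-1,4-xylan binding	6	37160
Lignocellulose-binding modules	CBM9	Xylan and cellulose binding	9	6772
Lignocellulose-binding modules	CBM16	Cellulose and glucomannan binding	9	52702
Lignocellulose-binding modules	CBM23	Mannan binding	1	108
Lignocellulose-binding modules	CBM31	beta-1,3-xylan binding	2	1040
Lignocellulose-binding modules	CBM32	Galactose and lactose binding	3	4634
Lignocellulose-binding modules	CBM35	Xylan, mannan and beta-galactan binding	6	24400
Lignocellulose-binding modules	CBM37	Cellulose and xylan binding	10	33850
Lignocellulose-binding modules	CBM42	Arabinoxylan binding	2	6504
Lignocellulose-binding modules	CBM44	Cellulose and xyloglucan binding	1	3110
Lignocellulose-binding modules	CBM46	Cellulose binding	2	204
Lignocellulose-binding modules	CBM51	Galactose binding	4	6940
Lignocellulose-binding modules	CBM54	Xylan and glucan binding	3	560
Lignocellulose-binding modules	CBM61	beta-1,4-galactan binding	5	38294
Lignocellulose-binding modules	CBM67	L-rhamnose binding	4	146
Cellulases and hemicellulases	GH1	beta-glucosidase; beta-galactosidase; beta-mannosidase; beta-glucuronidase; beta-xylosidase	29	49444
Cellulases and hemicellulases	GH3	beta-glucosidase; beta-xylosidase; alpha-L-fucosidase	29	100644
Cellulases and hemicellulases	GH5	Endo-beta-1,4-glucanase; endo-beta-1,4-xylanase; beta-glucosidase; beta-mannosidase; cellobiohydrolase (subfamilies)	16	84872
Cellulases and hemicellulases	GH8	Endoglucanase; endo-1,4-beta-xylanase	1	4926
Cellulases and hemicellulases	GH9	Endoglucanase; endo-beta-1,3(4)-glucanase; beta-glucosidase; cellobiohydrolase	16	100654
Cellulases and hemicellulases	GH16	Endo-1,3(4)-beta-glucanase; xyloglucanase; endo-beta-1,4-galactosidase	3	4480
Cellulases and hemicellulases	GH26	beta-mannanase; beta-1,3-xylanase; endo-beta-1,3(4)-glucanase	7	59378
Cellulases and hemicellulases	GH30_8	Endo-beta-1,4-xylanase; beta-glucosidase; beta-glucuronidase; beta-xylosidase	1	4114
Cellulases and hemicellulases	GH44	Endoglucanase; xyloglucanase	1	11206
Cellulases and hemicellulases	GH48	Cellobiohydrolase; endo-beta-1,4-glucanase	3	20574
Cellulases and hemicellulases	GH51	Endoglucanase; endo-beta-1,4-xylanase; beta-xylosidase; alpha-L-arabinofuranosidase	8	32728
Cellulases and hemicellulases	GH74	Endoglucanase; cellobiohydrolase; xyloglucanase	7	40172
Cellulases and hemicellulases	GH81	Endo-beta-1,3-glucanase	1	6332
Cellulases and hemicellulases	GH116	beta-glucosidase; beta-xylosidase	1	1236
Hemicellulases	GH2	beta-galactosidase; beta-mannosidase; alpha-L-arabinofuranosidase	25	168714
Hemicellulases	GH4	alpha-glucosidase; alpha-galactosidase; alpha-glucuronidase	22	47864
Hemicellulases	GH10	Endo-beta-1,3(4)-xylanase	20	141490
Hemicellulases	GH11	Endo-beta-1,3(4)-xylanase	1	7380
Hemicellulases	GH27	alpha-galactosidase	1	8546
Hemicellulases	GH29	alpha-L-fucosidase	6	25280
Hemicellulases	GH31	alpha-glucosidase; alpha-galactosidase; alpha-xylosidase	14	47634
Hemicellulases	GH35	beta-galactosidase	2	16812
Hemicellulases	GH36	alpha-galactosidase	11	61974
Hemicellulases	GH37	alpha-trehalase	1	11212
Hemicellulases	GH38	alpha-mannosidase	8	26766
Hemicellulases	GH39	beta-xylosidase	6	38952
Hemicellulases	GH42	beta-galactosidase; alpha-L-arabinopyranosidase	8	15742
Hemicellulases	GH43	beta-xylosidase; alpha-L-arabinofuranosidase (subfamilies)	23	139416
Hemicellulases	GH52	beta-xylosidase	1	11314
Hemicellulases	GH53	Endo-beta-1,4-galactanase	5	46350
Hemicellulases	GH76	alpha-1,6-mannanase	7	17582
Hemicellulases	GH78	alpha-L-rhamnosidase	3	156
Hemicellulases	GH95	alpha-L-fucosidase; alpha-L-galactosidase	11	44410
Hemicellulases	GH106	alpha-L-rhamnosidase	8	55788
Hemicellulases	GH113	beta-mannanase	1	1470
Hemicellulases	GH120	beta-xylosidase	5	17812
Hemicellulases	GH125	Exo-alpha-1,6-mannosidase	1	12
Hemicellulases	GH127	beta-L-arabinofuranosidase	3	31670
Hemicellulases	GH137	beta-L-arabinofuranosidase	2	38
Hemicellulases	GH141	alpha-L-fucosidase	1	9140
Hemicellulases	GH142	beta-L-arabinofuranosidase	1	56
Hemicellulases and pectin	CE1	Acetyl xylan esterase; cinnamoyl esterase; feruloyl esterase; carboxylesterase	44	60674
Hemicellulases and pectin	CE3	Acetyl xylan esterase	17	39112
Hemicellulases and pectin	CE4	Acetyl xylan esterase; chitin deacetylase	95	152940
Hemicellulases and pectin	CE6	Acetyl xylan esterase	1	978
Hemicellulases and pectin	CE7	Acetyl xylan esterase	16	50096
Hemicellulases and pectin	CE8	Pectin methylesterase	8	16440
Hemicellulases and pectin	CE9	N-acetylglucosamine 6-phosphate deacetylase	20	47026
Hemicellulases and pectin	CE10	Arylesterase; carboxyl esterase	21	53606
Hemicellulases and pectin	CE12	Rhamnogalacturonan acetylesterase; acetyl xylan esterase	11	26316
Hemicellulases and pectin	GH28	Polygalacturonase; rhamnogalacturonase	5	28470
Hemicellulases and pectin	GH67	Xylan alpha-1,2-glucuronidase	4	29962
Hemicellulases and pectin	GH88	beta-glucuronyl hydrolase	2	9944
Hemicellulases and pectin	GH105	Rhamnogalacturonyl hydrolase	10	49172
Hemicellulases and pectin	GH115	Xylan alpha-1,2-glucuronidase	1	12512
Hemicellulases and pectin	GH138	alpha-galacturonidase	2	2772
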