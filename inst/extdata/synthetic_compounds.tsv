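compound_id	name	mass
C001	glycine	75.03203
C002	alanine	89.04768
C003	serine	105.04259
C004	proline	115.06333
C005	valine	117.07898
C006	threonine	119.05824
C007	leucine-isoleucine	131.09463
C008	aspartate	133.03751
C009	glutamine	146.06914
C010	lysine	146.10553
C011	glutamate	147.05316
C012	methionine	149.05105
C013	histidine	155.06948
C014	phenylalanine	165.07898
C015	arginine	174.11168
C016	tyrosine	181.07389
C017	tryptophan	204.08988
C018	gamma-aminobutyrate	103.06333
C019	dopamine	153.07898
C020	serotonin	176.09496
C021	5-hydroxytryptophan	220.08479
C022	kynurenine	208.08479
C023	levodopa	197.06881
C024	N-acetylserotonin	218.10553
C025	carnitine	161.10519
C026	acetylcarnitine	203.11576
C027	glucose	180.06339
C028	glucose-6-phosphate	260.02972
C029	trehalose	342.11621
C030	pyruvate	88.01604
C031	lactate	90.03169
C032	citrate	192.02700
C033	succinate	118.02661
C034	choline	103.09971
C035	phosphocholine	183.06604
C036	ethanolamine	61.05276
C037	phosphoethanolamine	141.01909
C038	pantothenate	219.11067
C039	sphingosine	299.28243
C040	anthranilate	137.04768
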