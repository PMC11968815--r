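taxid	parent
131567	1
2	131567
2157	131567
2759	131567
10239	1
544448	2
31969	544448
186328	31969
2093	186328
2132	186328
1224	2
1236	1224
91347	1236
543	91347
561	543
562	561
1239	2
186801	1239
186802	186801
216572	186802
9604	33208
9606	9604
33208	2759
4751	2759
4890	4751
4891	4890
4892	4891
4932	4892
28211	1224
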