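gene_id	microcosm	pictar	mirnaorg	targetscan
CG15544	1.2446	0.0137	NA	0.1564
CG1623	14.609	NA	20.3535	13.6183
CG17712	16.4402	NA	12.5865	9.835
CG3678	22.2661	NA	15.647	9.835
CG4893	19.6009	NA	21.6375	20.3047
fray	NA	NA	NA	1.0625
Ggamma1	NA	10.0845	3.4702	18.7955
inx2	0.0986	NA	10.2664	NA
Nek2	29.1504	NA	13.6972	9.835
nord	NA	0.012	3.5694	0.3669
Paf-AHalpha	2.4176	NA	NA	NA
Pif1B	8.5626	NA	5.5158	18.7342
sna	0.581	NA	0.3121	6.6337
tor	16.4688	NA	11.385	16.3916
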