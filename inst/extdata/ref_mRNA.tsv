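feature_id	mean_L	mean_H	log2fc
ENSGALT00000002892	2165799	592843.8	-1.73992
ENSGALT00000056823	959658	234419	-1.90418
MTCONS_00058597	282406.2	119824.5	-1.10759
ENSGALT00000083486	371304	112513	-1.59325
ENSGALT00000027531	24398.34	84566.61	1.922561
ENSGALT00000019639	168144	70319	-1.12846
ENSGALT00000068577	26347	59925.02	1.314775
MTCONS_00056041	545124.6	59193.44	-3.07382
ENSGALT00000024496	159362	58913	-1.30639
MTCONS_00043232	132570.9	58860.85	-1.04213
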