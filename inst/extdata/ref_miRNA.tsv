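feature_id	mean_L	mean_H	log2fc
miR-92a_1	35074	7418	-1.78953
miR-191-5p	27280.33	9062.833	-1.13806
miR-100-5p_1	10997.17	24209	1.590181
miR-126-3p	22141	2196.833	-2.88145
miR-26c_1	412.5	21795.17	6.17524
miR-126-3p_1	2961	17333.33	3.001163
miR-92a_2	1384.167	17077	4.076735
novel_mir182	7226.5	303.3333	-4.12255
miR-429	2103	4070.5	1.404527
miR-125b_1	2115.667	3120.167	1.012281
miR-10a-5p	4031	995	-1.5666
miR-24-3p	3729.667	1236.5	-1.14101
novel_mir4	3346.167	1189.333	-1.04059
let-7b	3158.333	1033.833	-1.15939
miR-146a_1	3093.333	716.6667	-1.65802
miR-140-5p_1	1253.667	2049.5	1.160888
miR-146a-5p_1	1103.667	2170.167	1.427271
miR-429_1	3218.167	42.16667	-5.80222
miR-10a_2	638.8333	2542.5	2.444506
miR-103_1	1747.5	602	-1.08569
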