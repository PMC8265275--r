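feature_id	mean_L	mean_H	log2fc
LTCONS_00020831	79374.24	168343.7	1.213923
LTCONS_00020832	230312.4	5371.91	-5.29276
LTCONS_00055244	113243	49591	-1.06202
LTCONS_00029013	158164.8	4411.57	-5.03474
LTCONS_00040763	73239.73	30631.24	-1.12837
LTCONS_00046846	77193.92	3376.17	-4.38577
LTCONS_00000249	50129.79	19380	-1.24184
LTCONS_00025768	47501.63	20827.96	-1.0602
LTCONS_00010452	21954.88	40581.95	1.015552
LTCONS_00000621	45945.24	12643.59	-1.73225
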