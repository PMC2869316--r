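condition	genotype	category	events	total	decimals
bone_marrow	wild_type	fragments_breaks	0	1919	0
bone_marrow	wild_type	fusion	0	1919	0
bone_marrow	wild_type	sfe	7	1919	1
bone_marrow	ogg1_null	fragments_breaks	0	1980	0
bone_marrow	ogg1_null	fusion	0	1980	0
bone_marrow	ogg1_null	sfe	14	1980	1
mef_3pct_o2	wild_type	fragments_breaks	0	1087	0
mef_3pct_o2	wild_type	fusion	0	1087	0
mef_3pct_o2	wild_type	sfe	35	1087	1
mef_3pct_o2	ogg1_null	fragments_breaks	0	1140	0
mef_3pct_o2	ogg1_null	fusion	0	1140	0
mef_3pct_o2	ogg1_null	sfe	47	1140	1
mef_20pct_o2	wild_type	fragments_breaks	1	846	1
mef_20pct_o2	wild_type	fusion	0	846	0
mef_20pct_o2	wild_type	sfe	38	846	1
mef_20pct_o2	ogg1_null	fragments_breaks	7	946	1
mef_20pct_o2	ogg1_null	fusion	1	946	2
mef_20pct_o2	ogg1_null	sfe	79	946	1
mef_paraquat	wild_type	fragments_breaks	1	993	1
mef_paraquat	wild_type	fusion	1	993	1
mef_paraquat	wild_type	sfe	41	993	1
mef_paraquat	ogg1_null	fragments_breaks	0	983	0
mef_paraquat	ogg1_null	fusion	2	983	1
mef_paraquat	ogg1_null	sfe	183	983	1
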