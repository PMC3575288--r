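plasmid	conc_ng_ul
pNI1	151.4
pHD1	208.4
pNN1	194.0
pNG1	202.1
pNI2	197.7
pHD2	263.6
pNN2	260.9
pNG2	196.6
pNI3	130.9
pHD3	225.9
pNN3	291.4
pNG3	167.7
pNI4	102.3
pHD4	90.7
pNN4	278.9
pNG4	109.2
pNI5	284.6
pHD5	259.8
pNN5	124.6
pNG5	91.3
pNI6	209.2
pHD6	175.5
pNN6	92.0
pNG6	83.7
pNI7	271.6
pHD7	92.4
pNN7	237.5
pNG7	168.5
pNI8	150.4
pHD8	115.9
pNN8	244.2
pNG8	226.2
pNI9	82.0
pHD9	177.1
pNN9	204.5
pNG9	219.6
pNI10	174.4
pHD10	168.3
pNN10	195.6
pNG10	180.2
pLR_NI	93.8
pLR_HD	296.0
pLR_NN	156.6
pLR_NG	263.6
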