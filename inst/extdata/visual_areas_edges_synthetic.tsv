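area_a	area_b
lh_V1	lh_V2v
lh_V1	lh_V2d
lh_V2v	lh_V3v
lh_V2d	lh_V3d
lh_V3v	lh_hV4
lh_V3d	lh_V3a
lh_V3d	lh_LO1
lh_hV4	lh_VO1
lh_VO1	lh_VO2
lh_VO2	lh_PHC1
lh_PHC1	lh_PHC2
lh_LO1	lh_LO2
lh_LO2	lh_TO1
lh_TO1	lh_TO2
lh_V3a	lh_V3b
lh_V3b	lh_LO1
lh_V3a	lh_IPS0
lh_IPS0	lh_IPS1
lh_IPS1	lh_IPS2
lh_IPS2	lh_IPS3
lh_IPS3	lh_IPS4
lh_IPS4	lh_IPS5
lh_IPS5	lh_SPL1
lh_IPS4	lh_FEF
rh_V1	rh_V2v
rh_V1	rh_V2d
rh_V2v	rh_V3v
rh_V2d	rh_V3d
rh_V3v	rh_hV4
rh_V3d	rh_V3a
rh_V3d	rh_LO1
rh_hV4	rh_VO1
rh_VO1	rh_VO2
rh_VO2	rh_PHC1
rh_PHC1	rh_PHC2
rh_LO1	rh_LO2
rh_LO2	rh_TO1
rh_TO1	rh_TO2
rh_V3a	rh_V3b
rh_V3b	rh_LO1
rh_V3a	rh_IPS0
rh_IPS0	rh_IPS1
rh_IPS1	rh_IPS2
rh_IPS2	rh_IPS3
rh_IPS3	rh_IPS4
rh_IPS4	rh_IPS5
rh_IPS5	rh_SPL1
rh_IPS4	rh_FEF
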