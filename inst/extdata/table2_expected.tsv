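taxon	stroma_immature	stroma_mature	SFP	ascospores_fully_ejected	ascospores_semiejected
#1	1	1	1	1	1
#2	1	1	0	0	0
#4	1	1	1	0	0
#5	1	1	1	1	1
#6	1	1	1	1	0
#13	0	0	0	0	1
#14	0	0	0	1	0
#15	1	1	1	0	0
#16	1	0	0	1	0
#17	1	0	0	0	0
S.hepiali	1	1	1	1	1
AB067719-type	1	1	1	1	1
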