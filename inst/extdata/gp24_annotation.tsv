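peak	structure	galactose_count	sialic_acid_count	core_fucose	bisecting_glcnac
GP1	FA1	0	0	1	0
GP2	A2	0	0	0	0
GP3	A2B	0	0	0	1
GP4	FA2	0	0	1	0
GP5	M5	0	0	0	0
GP6	FA2B	0	0	1	1
GP7	A2G1	1	0	0	0
GP8	FA2[6]G1	1	0	1	0
GP9	FA2[3]G1	1	0	1	0
GP10	FA2[6]BG1	1	0	1	1
GP11	FA2[3]BG1	1	0	1	1
GP12	A2G2	2	0	0	0
GP13	A2BG2	2	0	0	1
GP14	FA2G2	2	0	1	0
GP15	FA2BG2	2	0	1	1
GP16	FA2G1S1	1	1	1	0
GP17	A2G2S1	2	1	0	0
GP18	FA2G2S1	2	1	1	0
GP19	FA2BG1S1	1	1	1	1
GP20	FA2BG2S1	2	1	1	1
GP21	A2G2S2	2	2	0	0
GP22	FA2G2S2	2	2	1	0
GP23	FA2BG2S2	2	2	1	1
GP24	A2BG2S2	2	2	0	1
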