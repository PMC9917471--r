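gene	green_01	green_02	green_03	red_01	red_02	red_03
ADF2	1036	643	717	680	670	542
CYB5	1188	1349	814	911	1681	1229
iPGAM	379	252	251	313	280	408
SCL13	130	145	204	212	189	86
TRXL3-3	712	975	366	383	701	330
VHA-H	324	516	389	440	400	328
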