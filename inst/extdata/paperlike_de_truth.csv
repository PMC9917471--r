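gene,log2fc,fdr,mean_count
ADF2,0,1,810.812150811156
CYB5,0,1,1216.21822621673
iPGAM,0,1,304.054556554183
SCL13,0,1,152.027278277092
TRXL3-3,0,1,506.757594256972
VHA-H,0,1,405.406075405578
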