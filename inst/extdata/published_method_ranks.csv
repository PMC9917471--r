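experiment,method,gene,rank,stability_value
green_vs_red,geNorm,CYB5,1,0.33
green_vs_red,geNorm,ADF2,2,0.33
green_vs_red,geNorm,TRXL3-3,3,0.54
green_vs_red,geNorm,VHA-H,4,1.11
green_vs_red,geNorm,iPGAM,5,1.33
green_vs_red,geNorm,SCL13,6,1.90
green_vs_red,NormFinder,TRXL3-3,1,0.71
green_vs_red,NormFinder,VHA-H,2,0.77
green_vs_red,NormFinder,CYB5,3,0.81
green_vs_red,NormFinder,ADF2,4,1.09
green_vs_red,NormFinder,iPGAM,5,1.49
green_vs_red,NormFinder,SCL13,6,2.88
green_vs_red,BestKeeper,TRXL3-3,1,0.40
green_vs_red,BestKeeper,CYB5,2,0.53
green_vs_red,BestKeeper,SCL13,3,0.53
green_vs_red,BestKeeper,ADF2,4,0.57
green_vs_red,BestKeeper,iPGAM,5,0.72
green_vs_red,BestKeeper,VHA-H,6,1.12
green_vs_red,DeltaCt,CYB5,1,0.83
green_vs_red,DeltaCt,ADF2,2,0.83
green_vs_red,DeltaCt,SCL13,3,0.92
green_vs_red,DeltaCt,TRXL3-3,4,1.10
green_vs_red,DeltaCt,iPGAM,5,1.28
green_vs_red,DeltaCt,VHA-H,6,1.41
leaf_vs_stem,geNorm,CYB5,1,0.77
leaf_vs_stem,geNorm,ADF2,2,0.77
leaf_vs_stem,geNorm,TRXL3-3,3,1.01
leaf_vs_stem,geNorm,VHA-H,4,1.07
leaf_vs_stem,geNorm,iPGAM,5,1.22
leaf_vs_stem,geNorm,SCL13,6,2.41
leaf_vs_stem,NormFinder,TRXL3-3,1,0.30
leaf_vs_stem,NormFinder,VHA-H,2,0.30
leaf_vs_stem,NormFinder,ADF2,3,1.18
leaf_vs_stem,NormFinder,CYB5,4,1.34
leaf_vs_stem,NormFinder,iPGAM,5,1.55
leaf_vs_stem,NormFinder,SCL13,6,4.73
leaf_vs_stem,BestKeeper,TRXL3-3,1,0.44
leaf_vs_stem,BestKeeper,iPGAM,2,0.47
leaf_vs_stem,BestKeeper,CYB5,3,0.77
leaf_vs_stem,BestKeeper,ADF2,4,0.89
leaf_vs_stem,BestKeeper,SCL13,5,0.92
leaf_vs_stem,BestKeeper,VHA-H,6,1.23
leaf_vs_stem,DeltaCt,TRXL3-3,1,0.93
leaf_vs_stem,DeltaCt,CYB5,2,1.03
leaf_vs_stem,DeltaCt,iPGAM,3,1.08
leaf_vs_stem,DeltaCt,ADF2,4,1.10
leaf_vs_stem,DeltaCt,VHA-H,5,1.38
leaf_vs_stem,DeltaCt,SCL13,6,1.54
drought,geNorm,TRXL3-3,1,1.54
drought,geNorm,ADF2,2,1.54
drought,geNorm,CYB5,3,1.98
drought,geNorm,iPGAM,4,3.40
drought,geNorm,SCL13,5,4.41
drought,geNorm,VHA-H,6,6.82
drought,NormFinder,TRXL3-3,1,0.77
drought,NormFinder,ADF2,2,0.77
drought,NormFinder,iPGAM,3,2.81
drought,NormFinder,CYB5,4,2.91
drought,NormFinder,SCL13,5,6.62
drought,NormFinder,VHA-H,6,11.27
drought,BestKeeper,TRXL3-3,1,0.85
drought,BestKeeper,SCL13,2,0.92
drought,BestKeeper,iPGAM,3,1.11
drought,BestKeeper,ADF2,4,1.23
drought,BestKeeper,CYB5,5,1.50
drought,BestKeeper,VHA-H,6,10.35
drought,DeltaCt,SCL13,1,3.89
drought,DeltaCt,TRXL3-3,2,3.90
drought,DeltaCt,iPGAM,3,4.01
drought,DeltaCt,ADF2,4,4.04
drought,DeltaCt,CYB5,5,4.07
drought,DeltaCt,VHA-H,6,14.08
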