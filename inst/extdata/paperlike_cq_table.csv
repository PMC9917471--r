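sample_id,group,gene,replicate,cq,efficiency
green_01,green,ADF2,1,31.8591546825615,1.93
green_01,green,ADF2,2,31.7151087720803,1.93
green_01,green,CYB5,1,30.7309359606343,1.88
green_01,green,CYB5,2,30.6668132950607,1.88
green_01,green,iPGAM,1,37.5726221716017,1.8
green_01,green,iPGAM,2,37.7328806006012,1.8
green_01,green,SCL13,1,36.8443428251183,1.76
green_01,green,SCL13,2,36.5831439508098,1.76
green_01,green,TRXL3-3,1,34.1948053412025,1.97
green_01,green,TRXL3-3,2,34.1045093010709,1.97
green_01,green,VHA-H,1,32.6153706796531,1.85
green_01,green,VHA-H,2,32.8992285594138,1.85
green_02,green,ADF2,1,31.3223687453476,1.93
green_02,green,ADF2,2,31.2487572344547,1.93
green_02,green,CYB5,1,31.1148202241698,1.88
green_02,green,CYB5,2,30.9063308671265,1.88
green_02,green,iPGAM,1,37.5861088087984,1.8
green_02,green,iPGAM,2,37.5995720638921,1.8
green_02,green,SCL13,1,36.1923538561291,1.76
green_02,green,SCL13,2,36.4598247333252,1.76
green_02,green,TRXL3-3,1,33.3860248272015,1.97
green_02,green,TRXL3-3,2,33.3193033424591,1.97
green_02,green,VHA-H,1,32.8714148847589,1.85
green_02,green,VHA-H,2,32.7110695509502,1.85
green_03,green,ADF2,1,31.7198195168475,1.93
green_03,green,ADF2,2,31.9185417660687,1.93
green_03,green,CYB5,1,31.1421339130903,1.88
green_03,green,CYB5,2,30.867919778945,1.88
green_03,green,iPGAM,1,37.4242257177441,1.8
green_03,green,iPGAM,2,37.4170119157776,1.8
green_03,green,SCL13,1,37.5343984711139,1.76
green_03,green,SCL13,2,37.5552454472742,1.76
green_03,green,TRXL3-3,1,33.9517657985193,1.97
green_03,green,TRXL3-3,2,34.1957023431338,1.97
green_03,green,VHA-H,1,33.5354364349063,1.85
green_03,green,VHA-H,2,33.739775361705,1.85
red_01,red,ADF2,1,31.5728025740836,1.93
red_01,red,ADF2,2,31.7585097109673,1.93
red_01,red,CYB5,1,31.960885794615,1.88
red_01,red,CYB5,2,31.7617149764057,1.88
red_01,red,iPGAM,1,38.1240536897437,1.8
red_01,red,iPGAM,2,37.81573037486,1.8
red_01,red,SCL13,1,37.1194504428354,1.76
red_01,red,SCL13,2,37.3731295429981,1.76
red_01,red,TRXL3-3,1,34.74665718981,1.97
red_01,red,TRXL3-3,2,34.8128102719672,1.97
red_01,red,VHA-H,1,33.9880997970674,1.85
red_01,red,VHA-H,2,33.3876409488513,1.85
red_02,red,ADF2,1,30.7919620185178,1.93
red_02,red,ADF2,2,30.4769318314956,1.93
red_02,red,CYB5,1,29.6925345850107,1.88
red_02,red,CYB5,2,29.4496114891317,1.88
red_02,red,iPGAM,1,35.9483984507171,1.8
red_02,red,iPGAM,2,36.1074306996278,1.8
red_02,red,SCL13,1,35.192434097614,1.76
red_02,red,SCL13,2,35.4561858935658,1.76
red_02,red,TRXL3-3,1,33.6736821539751,1.97
red_02,red,TRXL3-3,2,33.3745404372822,1.97
red_02,red,VHA-H,1,31.5139575821825,1.85
red_02,red,VHA-H,2,31.1886916552131,1.85
red_03,red,ADF2,1,31.6719299222074,1.93
red_03,red,ADF2,2,31.3093017309821,1.93
red_03,red,CYB5,1,30.7540183515868,1.88
red_03,red,CYB5,2,30.9010713783198,1.88
red_03,red,iPGAM,1,37.7063175683373,1.8
red_03,red,iPGAM,2,37.7742076957733,1.8
red_03,red,SCL13,1,36.9125247487678,1.76
red_03,red,SCL13,2,37.0594925837717,1.76
red_03,red,TRXL3-3,1,34.1108561272745,1.97
red_03,red,TRXL3-3,2,34.2236646883581,1.97
red_03,red,VHA-H,1,33.3505163405746,1.85
red_03,red,VHA-H,2,33.5542338132413,1.85
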