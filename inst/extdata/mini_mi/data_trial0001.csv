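ch1,ch2,ch3
0.0003870103040373718,0.73578252196198601,-2.3136279288677546
-2.1877004587806557,-0.19954911797188862,-1.5580312166151558
0.20588357919516415,-1.3059311039219554,1.8990300495739802
-0.23738530070841843,-0.70170962410952853,0.50911287238610714
0.77935856252769764,-0.47296117024553186,-0.020058225150996211
-0.57645779998795155,1.5611229630427519,-2.3426668257690304
1.3998079757867283,0.72880137377519594,-0.076046572633525281
0.095319538866766695,0.33679844038708129,1.1122753549529873
-0.16150468145154537,0.18703120646181653,-0.17404898457874149
-0.087111916400914161,-1.4708085498217196,-0.19162562702403885
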