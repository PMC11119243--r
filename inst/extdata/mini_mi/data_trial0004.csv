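ch1,ch2,ch3
0.51614634303046425,-0.45669902062604895,-0.69049985638192357
0.47470659262995507,-0.073720026165099151,-0.62757109776080466
-0.87768466243848919,-2.0388020448783597,-2.2930988215346417
1.4405446455082751,1.4986650741063432,0.48451584509996665
-1.8416422796242577,0.016873988380644855,0.46560182103384379
0.40885941788415814,1.730047859830472,1.5139314715431356
-0.23812309358923109,-1.4821425048590691,0.29869476424354341
0.28414340250605769,-0.13664771732872055,1.266091843325774
-0.98879489238080909,-2.2420695768003891,-1.6048517272694511
-0.43079815992327763,0.018225524302401847,0.98255081859603277
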