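ch1,ch2,ch3
-0.41073132197406659,-1.6803875302470752,-0.43692811484976818
-0.067136351664583885,-0.2568668314389973,0.71339560318698125
-0.076974929481786608,-0.23578874107613032,0.88819681042272125
1.6219968092223518,0.040418512852833766,-0.1630325339083909
0.86805501977561783,1.0277576900668124,1.1846607050849927
0.2420596517867406,0.10652421204129023,-1.145783578303295
0.016268004982044559,-1.7367719413382396,-0.70870636244563978
1.1104142679717093,2.2808661039660794,0.20145273302253996
1.1904844774434591,0.130684261239366,0.56375470352961055
-0.1686414505100883,-0.35206904880557333,-0.27091908935819237
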