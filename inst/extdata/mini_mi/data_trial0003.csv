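ch1,ch2,ch3
-0.92365457544947793,0.57060765095610855,-0.83870301978383088
1.485902232317839,0.75505634615942174,0.18052235623674723
-0.41925580600922574,-1.0674651005110425,0.31394804470932242
-0.038186165145645413,0.10339826667472593,-0.50058431616707166
0.42060462824596001,0.37275049419698358,0.019818258330587563
1.1218937922989889,-1.1168523946555045,-1.3124066414128646
0.33244050151256832,-1.1148815517827635,0.56766896844903325
-0.99482591274126697,1.5914337943377237,-0.086635116036026513
-0.76939016570310637,-0.66769561061052896,0.27619747873566081
0.24737526374033011,1.0412685707955447,0.34727231426354899
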