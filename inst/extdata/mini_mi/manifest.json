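{"type":"epoched","storage":"csv","fs":100,"n_trials":4,"n_channels":3,"n_samples":10,"channel_names":["ch1","ch2","ch3"],"labels":[2,1,1,2],"label_map":{"1":1,"2":2}}
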