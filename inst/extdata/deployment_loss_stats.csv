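id,loss_mean_percent,loss_sd_percent,burst_mean_ms,burst_sd_ms,burst_modal_ms
1,0.95,0.77,111.55,532.89,64
2,0.97,0.55,92.07,242.97,64
3,2.02,0.78,104.22,531.12,64
4,1.14,1.12,101.25,532.89,64
5,1.51,1.17,114.85,529.04,64
6,0.32,0.37,143.04,240.10,64
7,1.83,1.04,139.44,542.15,64
8,1.25,1.26,123.64,242.97,64
9,1.31,1.02,174.26,527.90,64
10,1.27,1.07,115.10,542.15,64
11,1.84,1.11,106.55,542.59,64
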