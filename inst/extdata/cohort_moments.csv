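parameter,sequence,benign_mean,benign_sd,malignant_mean,malignant_sd
D,SSEPI,1.17,0.34,0.73,0.18
D,SMS,1.21,0.34,0.74,0.18
beta,SSEPI,0.86,0.06,0.77,0.06
beta,SMS,0.86,0.05,0.79,0.05
mu,SSEPI,3.06,0.63,3.39,0.42
mu,SMS,3.20,0.48,3.50,0.34
adc,SSEPI,1.30,0.36,0.82,0.20
adc,SMS,1.33,0.36,0.83,0.20
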