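dataset,model,metric,global_mean
wheat,M1,MSE,0.5951
wheat,M2,MSE,0.7645
wheat,M3,MSE,0.9035
wheat,M4,MSE,0.5769
wheat,M5,MSE,0.6183
wheat,M6,MSE,0.6645
wheat,M3,NRMSE,1.0004
wheat,M4,NRMSE,0.8123
maize,M1,MSE,0.2059
maize,M2,MSE,0.2336
maize,M3,MSE,0.2603
maize,M4,MSE,0.2215
maize,M5,MSE,0.2099
maize,M6,MSE,0.2396
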