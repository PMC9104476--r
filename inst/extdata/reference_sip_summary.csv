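subject,mean_mL,sd_mL,error_pct
F20,23.83,5.13,15.35
F22,19.42,5.17,22.94
F28,8.73,3.05,29.05
M20,12.19,4.33,34.10
M21,11.40,3.71,30.04
M211,13.67,3.15,17.34
M25,18.72,6.14,28.50
M251,7.14,2.96,40.73
M27,12.73,3.98,28.01
M29,15.13,5.99,32.71
M67,21.33,8.75,43.67
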