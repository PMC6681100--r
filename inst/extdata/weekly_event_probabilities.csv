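tail,straw,space,w1,w2,w3,w4,w5,w6,w7,w8,w9,w10
docked,yes,low,3.61,2.55,3.98,2.55,3.24,1.91,0.24,0.50,1.03,0.76
docked,yes,high,6.72,4.80,7.40,4.80,6.06,3.62,0.47,0.95,1.97,1.45
docked,no,low,9.38,6.76,10.29,6.76,8.48,5.11,0.67,1.36,2.80,2.07
docked,no,high,16.61,12.25,18.09,12.25,15.15,9.40,1.28,2.59,5.26,3.91
undocked,yes,low,10.09,7.29,11.07,7.29,9.13,5.52,0.73,1.47,3.03,2.24
undocked,yes,high,17.77,13.14,19.33,13.14,16.22,10.12,1.39,2.80,5.68,4.23
undocked,no,low,23.68,17.85,25.60,17.85,21.75,13.91,1.98,3.97,7.95,5.96
undocked,no,high,37.40,29.50,39.85,29.50,34.87,23.73,3.75,7.38,14.27,10.88
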