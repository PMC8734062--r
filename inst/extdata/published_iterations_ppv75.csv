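# reference_table: test iterations needed to reach a target PPV
# target_ppv=0.75
ln_LR+,0.02,0.05,0.07,0.1,0.15,0.2
0.50,9.98,8.09,7.37,6.59,5.67,4.97
1.00,4.99,4.04,3.69,3.30,2.83,2.48
1.50,3.33,2.70,2.46,2.20,1.89,1.66
2.00,2.50,2.02,1.84,1.65,1.42,1.24
2.50,2.00,1.62,1.47,1.32,1.13,0.99
3.00,1.66,1.35,1.23,1.10,0.94,0.83
3.50,1.43,1.16,1.05,0.94,0.81,0.71
4.00,1.25,1.01,0.92,0.82,0.71,0.62
4.50,1.11,0.90,0.82,0.73,0.63,0.55
5.00,1.00,0.81,0.74,0.66,0.57,0.50
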