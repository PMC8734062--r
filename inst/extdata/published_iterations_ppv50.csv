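# reference_table: test iterations needed to reach a target PPV
# target_ppv=0.5
ln_LR+,0.02,0.05,0.07,0.1,0.15,0.2
0.50,7.78,5.89,5.17,4.39,3.47,2.77
1.00,3.89,2.94,2.59,2.20,1.73,1.39
1.50,2.59,1.96,1.72,1.46,1.16,0.92
2.00,1.95,1.47,1.29,1.10,0.87,0.69
2.50,1.56,1.18,1.03,0.88,0.69,0.55
3.00,1.30,0.98,0.86,0.73,0.58,0.46
3.50,1.11,0.84,0.74,0.63,0.50,0.40
4.00,0.97,0.74,0.65,0.55,0.43,0.35
4.50,0.86,0.65,0.57,0.49,0.39,0.31
5.00,0.78,0.59,0.52,0.44,0.35,0.28
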