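# reference_table: test iterations needed to reach a target PPV
# target_ppv=0.99
ln_LR+,0.02,0.05,0.07,0.1,0.15,0.2
0.50,16.97,15.08,14.36,13.58,12.66,11.96
1.00,8.49,7.54,7.18,6.79,6.33,5.98
1.50,5.66,5.03,4.79,4.53,4.22,3.99
2.00,4.24,3.77,3.59,3.40,3.16,2.99
2.50,3.39,3.02,2.87,2.72,2.53,2.39
3.00,2.83,2.51,2.39,2.26,2.11,1.99
3.50,2.42,2.15,2.05,1.94,1.81,1.71
4.00,2.12,1.88,1.80,1.70,1.58,1.50
4.50,1.89,1.68,1.60,1.51,1.41,1.33
5.00,1.70,1.51,1.44,1.36,1.27,1.20
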