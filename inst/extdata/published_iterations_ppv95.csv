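# reference_table: test iterations needed to reach a target PPV
# target_ppv=0.95
ln_LR+,0.02,0.05,0.07,0.1,0.15,0.2
0.50,13.67,11.78,11.06,10.28,9.36,8.66
1.00,6.84,5.89,5.53,5.14,4.68,4.33
1.50,4.56,3.93,3.69,3.43,3.12,2.89
2.00,3.42,2.94,2.77,2.57,2.34,2.17
2.50,2.73,2.36,2.21,2.06,1.87,1.73
3.00,2.28,1.96,1.84,1.71,1.56,1.44
3.50,1.95,1.68,1.58,1.47,1.34,1.24
4.00,1.71,1.47,1.38,1.29,1.17,1.08
4.50,1.52,1.31,1.23,1.14,1.04,0.96
5.00,1.37,1.18,1.11,1.03,0.94,0.87
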