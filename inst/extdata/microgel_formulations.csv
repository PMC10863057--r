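formulation,avg_peg,avg_dex,top_peg,top_dex,bottom_peg,bottom_dex,volume_ratio
soft,3.5,21.65,18.10,0.08,3.01e-4,26.82,3.79
intermediate1,3.5,30.97,30.00,0.05,0,35.05,6.88
intermediate2,2.2,32.48,29.99,0.05,0,35.05,11.48
intermediate3,5.3,28.88,30.01,0.05,0,35.06,4.24
stiff,4.0,39.36,44.75,0.04,0,43.22,9.26
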