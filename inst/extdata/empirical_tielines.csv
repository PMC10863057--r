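avg_peg,avg_dex,top_peg,top_dex,bottom_peg,bottom_dex
5.0,6.0,7.34,0.91,0.31,16.21
6.0,8.0,10.14,0.28,0.09,19.10
7.0,10.0,12.85,0.15,0.02,21.78
8.0,12.0,14.56,0.12,6.24e-4,26.56
11.0,18.0,25.97,0.06,0,31.24
13.0,24.0,35.31,0.04,0,38.00
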