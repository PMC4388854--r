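[fig3_N1: two funnels in series above leaf b; lambda_i = i]
((a:4,(b:7)#H1:6):1,((d:12,(#H1:8)#H2:9):10,(c:11,#H2:5):3):2);
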