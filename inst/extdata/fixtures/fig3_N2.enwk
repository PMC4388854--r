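[fig3_N2: same displayed trees with the reticulation order swapped; x = y = 1/2]
((a:4,((b:6.5)#H2:1)#H1:5.5):1,((d:12,#H2:17.5):10,(c:11,#H1:12.5):3):2);
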