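[fig5_N: three funnels with unidentifiable out-edges x=y=z=0.05; displays 7 trees; not tree-child/tree-sibling/galled]
((((((b:0.05)#H2:0.17,(d:0.05)#H3:0.29):0.05)#H1:0.18,#H2:0.27):0.13,a:0.55):0.21,(#H3:0.23,#H1:0.31,c:0.62):0.34);
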