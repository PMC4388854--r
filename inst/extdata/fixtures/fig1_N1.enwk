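[fig1_N1: two-reticulation network, unit lengths; displays three tree topologies]
((a:1,(b:1)#H1:1):1,((c:1,(#H1:1)#H2:1):1,(d:1,#H2:1):1):1);
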