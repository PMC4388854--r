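[fig1_N2: reticulations in the opposite order, unit lambda; same three topologies]
((((b:0.5)#H2:0.75)#H1:0.75,a:1):1,((#H1:1.75,c:1):1,(d:1,#H2:2.5):1):1);
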