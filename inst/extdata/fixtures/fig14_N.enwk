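[fig14_N: host network for the wishbone/crack illustrations; one edge carries two lengths]
((a:{1,1.5},(c:1)#H1:1):1,(b:1,#H1:1):1);
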