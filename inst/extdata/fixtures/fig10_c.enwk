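[fig10_c: three parallel middle nodes: indistinguishable from fig10_b, not isomorphic, same wishbones and cracks]
((a#H1:1,b#H2:1):1,(a#H1:1,b#H2:1):1,(a#H1:1,b#H2:1):1);
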