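[fig10_b: two parallel middle nodes to reticulate leaves a,b; unit lengths]
((a#H1:1,b#H2:1):1,(a#H1:1,b#H2:1):1);
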