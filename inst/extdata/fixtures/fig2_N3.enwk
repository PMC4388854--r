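[fig2_N3: galled cycle with hybrid taxon c and outgroup o]
(((((c:0.3)#H1:0.1,b:0.4):0.2,a:0.6):0.35,#H1:0.5):0.45,o:1);
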