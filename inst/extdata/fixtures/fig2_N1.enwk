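[fig2_N1: galled cycle with hybrid taxon b and outgroup o]
((((b:0.15)#H1:0.3,c:0.6):0.25,(#H1:0.2,a:0.55):0.3):0.5,o:1);
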