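[fig2_N2: galled cycle with hybrid taxon a and outgroup o; displays both reference trees]
(((((a:0.4)#H1:0.15,b:0.35):0.25,c:0.55):0.3,#H1:0.45):0.5,o:1);
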