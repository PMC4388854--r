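[fig2_T2: reference weighted tree ((b,c),a) with outgroup]
(((c:0.55,b:0.6):0.3,a:0.85):0.5,o:1);
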