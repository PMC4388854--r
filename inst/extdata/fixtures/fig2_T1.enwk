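[fig2_T1: reference weighted tree ((a,b),c) with outgroup]
(((b:0.35,a:0.55):0.25,c:0.55):0.8,o:1);
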