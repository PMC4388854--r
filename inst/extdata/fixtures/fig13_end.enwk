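[fig13_end: canonical form reached after R1, R2, R1]
((c:1,(a:1,b:1)#H1:2):1,#H1:{2,3});
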