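[fig14_R: a crack: two root-leaf paths sharing the root and the suffix to c]
(((c:1)#H1:1):1,(#H1:1):1);
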