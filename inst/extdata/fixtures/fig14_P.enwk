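[fig14_P: a root-leaf path: degenerately both a wishbone and a crack]
(a:1):1;
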