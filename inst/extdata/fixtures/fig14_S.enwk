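[fig14_S: a crack: a root-leaf path with two lengths on one edge]
(a:{1,1.5}):1;
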