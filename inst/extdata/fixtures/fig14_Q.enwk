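[fig14_Q: a wishbone: two root-leaf paths sharing only the root]
((a:1):1,(b:1):1);
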