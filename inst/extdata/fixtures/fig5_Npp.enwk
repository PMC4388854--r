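[fig5_Npp: canonical network displaying two tree topologies with no regular equivalent]
((b#H1:0.2,a:0.5):0.3,(b#H1:0.25,c:0.45):0.4);
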