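[fig7_T1prime: displayed tree with outdegree-1 root (0.5 stem)]
((b:0.35,a:0.55):0.25,c:0.55):0.8;
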