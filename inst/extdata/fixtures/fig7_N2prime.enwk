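[fig7_N2prime: outgroup lineage trimmed to a 0.5 root edge; displays the two fig7 trees]
((((a:0.4)#H1:0.15,b:0.35):0.25,c:0.55):0.3,#H1:0.45):0.5;
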