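[fig13_start: reduction exercise: one funnel whose suppression creates a transient multiedge]
((c:1,((a:1,b:1)#H2:1)#H1:1):1,(#H2:1,#H1:1):1);
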