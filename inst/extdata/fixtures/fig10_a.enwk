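[fig10_a: funnel-free clock-like network with direct length-2 edges; violates NELP]
((a#H1:1,b#H2:1):1,a#H1:2,b#H2:2);
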