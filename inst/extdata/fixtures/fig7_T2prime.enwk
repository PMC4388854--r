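[fig7_T2prime: second displayed tree (0.5 stem)]
((c:0.55,b:0.6):0.3,a:0.85):0.5;
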