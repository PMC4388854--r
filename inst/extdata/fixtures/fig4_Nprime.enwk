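[fig4_Nprime: shared canonical form of the fig3 pair: leaf b has indegree 3]
((b#H1:13,a:4):1,((d:12,b#H1:24):10,(c:11,b#H1:20):3):2);
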