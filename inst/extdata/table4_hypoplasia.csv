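locus,unaffected,affected
d1,17,0
D1,16,4
d2,13,0
D2,5,1
d3,15,2
D3,3,2
d4,11,0
D4,6,0
p2,25,1
P2,27,10
p3,26,11
P3,21,7
p4,32,7
P4,18,6
m1,34,4
M1,19,2
m2,29,5
M2,20,3
m3,25,10
M3,25,4
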