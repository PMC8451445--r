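rule,coverage,timing,requires_damage,requires_dna,group
A,decline,early,any,any,A
B,unknown,early,any,any,B
C,decline,late,any,any,C
D,unknown,late,any,any,D
E,no_decline,any,no,yes,E
F,no_decline,any,yes,any,F
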