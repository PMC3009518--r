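F1 gf1 0 0 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 1
F1 gm1 0 0 2 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 2 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1
F1 gf2 0 0 1 0 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 1 1 1 1 1 1
F1 gm2 0 0 2 0 1 2 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 2 2 2 2 1 1 2 2 1 2 2 2
F1 fa gf1 gm1 1 0 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 1
F1 mo gf2 gm2 2 0 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2
F1 c1 fa mo 1 0 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 1 1 1 1 1 1
F1 c2 fa mo 2 0 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 1 1 2
F1 c3 fa mo 1 0 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 1 1 1 2 1 1 1 1 1 1
F1 c4 fa mo 2 0 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 1 1 1 2 1 1 1 1 1 1
F1 c5 fa mo 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 1 1 1 2 1 1 1 1 1 1
F2 fa 0 0 1 0 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1
F2 mo 0 0 2 1 1 2 1 2 1 2 1 2 2 2 2 2 2 2 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F2 c1 fa mo 1 0 1 2 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 1
F2 c2 fa mo 2 0 1 2 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 1
F2 c3 fa mo 1 0 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 1 1 2 1 2 1 2
F2 c4 fa mo 2 0 1 2 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 1
F2 c5 fa mo 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 1
F2 c6 fa mo 2 0 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 1 1 2 1 2 1 2
F2 c7 fa mo 1 0 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 1 1 2 1 2 1 2
F2 c8 fa mo 2 0 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 1 1 2 1 2 1 2
F3 gf1 0 0 1 0 2 2 2 2 2 2 1 1 1 2 1 1 1 1 1 1 1 1 1 2 1 1 1 1 2 2 2 2 1 1 2 2 2 2 2 2
F3 gm1 0 0 2 0 1 2 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 2 2 2 2 1 1 2 2 2 2 2 2
F3 gf2 0 0 1 1 1 2 1 2 1 2 2 2 2 2 2 2 2 2 1 1 1 2 1 2 1 1 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F3 gm2 0 0 2 1 1 2 1 2 1 2 1 2 1 2 1 2 1 2 1 1 2 2 2 2 1 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1
F3 fa gf1 gm1 1 0 1 2 1 2 1 2 1 2 2 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 2 2 2 2 1 1 2 2 2 2 2 2
F3 mo gf2 gm2 2 1 2 2 2 2 2 2 2 2 2 2 2 2 2 2 1 1 2 2 2 2 1 1 2 2 1 1 1 1 1 1 1 1 1 1 1 1
F3 c1 fa mo 1 0 1 2 1 2 1 2 2 2 2 2 2 2 2 2 1 1 1 2 1 2 1 1 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F3 c2 fa mo 2 0 1 2 1 2 1 2 2 2 2 2 2 2 2 2 1 1 1 2 1 2 1 1 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F3 c3 fa mo 1 0 1 2 1 2 1 2 2 2 2 2 2 2 2 2 1 1 1 2 1 2 1 1 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F3 c4 fa mo 2 1 2 2 2 2 2 2 1 2 2 2 1 2 1 2 1 1 1 2 1 2 1 1 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F3 c5 fa mo 1 1 1 2 1 2 1 2 2 2 2 2 2 2 2 2 1 1 1 2 1 2 1 1 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F3 c6 fa mo 2 0 1 2 1 2 1 2 2 2 2 2 2 2 2 2 1 1 1 2 1 2 1 1 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F4 gf1 0 0 1 1 1 2 1 2 1 2 2 2 2 2 2 2 2 2 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F4 gm1 0 0 2 0 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 2 2 2 1 1 2 2 2 2 2 2
F4 gf2 0 0 1 0 1 2 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 2 2 2 2 1 1 2 2 2 2 2 2
F4 gm2 0 0 2 0 2 2 2 2 2 2 1 2 1 2 1 2 1 2 1 1 1 1 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F4 fa gf1 gm1 1 1 2 2 2 2 2 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F4 mo gf2 gm2 2 1 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 2 2 2 2 1 1 2 2 2 2 2 2
F4 c1 fa mo 1 0 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 2 2 2 2 1 1 2 2 2 2 2 2
F4 c2 fa mo 2 1 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 2 2 2 1 1 2 2 2 2 2 2
F4 c3 fa mo 1 1 2 2 2 2 2 2 1 2 1 2 1 2 1 2 1 1 2 2 2 2 2 2 2 2 1 2 1 2 1 1 1 2 1 2 1 2
F4 c4 fa mo 2 1 2 2 2 2 2 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F4 c5 fa mo 1 0 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 2 2 2 2 1 1 2 2 2 2 2 2
F4 c6 fa mo 2 0 2 2 2 2 2 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F4 c7 fa mo 1 1 2 2 2 2 2 2 1 2 1 2 1 2 1 2 1 1 2 2 2 2 2 2 2 2 1 2 1 2 1 1 1 2 1 2 1 2
F4 c8 fa mo 2 1 2 2 2 2 2 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F4 c9 fa mo 1 0 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 2 2 2 2 1 1 2 2 2 2 2 2
F4 c10 fa mo 2 0 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 2 2 2 1 1 2 2 2 2 2 2
F4 c11 fa mo 1 0 2 2 2 2 2 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F4 c12 fa mo 2 0 2 2 2 2 2 2 1 2 1 2 1 2 1 2 1 1 2 2 2 2 2 2 2 2 1 2 1 2 1 1 1 2 1 2 1 2
F5 gf1 0 0 1 0 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 1 2 1 1 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 1
F5 gm1 0 0 2 0 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 2 2 2 2 1 1 2 2 2 2 2 2
F5 gf2 0 0 1 0 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 2 2 2 2 1 1 2 2 2 2 2 2
F5 gm2 0 0 2 0 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 1
F5 fa gf1 gm1 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 2 1 1 2 2 1 2 2 2 2 2 1 2 1 2 1 1 1 2 1 2 1 2
F5 mo gf2 gm2 2 0 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F5 c1 fa mo 1 0 1 2 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 1 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F5 c2 fa mo 2 0 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 2 2 2 2 2 2 2 2 1 2 1 2 1 1 1 2 1 2 1 2
F5 c3 fa mo 1 1 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 2 2 2 2 2 2 2 2 1 2 1 2 1 1 1 2 1 2 1 2
F5 c4 fa mo 2 1 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 2 2 2 2 2 2 2 2 1 2 1 2 1 1 1 2 1 2 1 2
F5 c5 fa mo 1 0 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 2 2 1 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1
F5 c6 fa mo 2 0 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 2 2 2 2 2 2 2 2 1 2 1 2 1 1 1 2 1 2 1 2
F5 c7 fa mo 1 0 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 2 2 1 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 1
F5 c8 fa mo 2 0 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 2 2 2 2 1 1 2 2 2 2 2 2
F5 c9 fa mo 1 1 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 2 2 2 2 1 1 2 2 2 2 2 2
F5 c10 fa mo 2 0 2 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 2 2 2 2 1 1 2 2 2 2 2 2
F6 fa 0 0 1 0 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 1 1 2 1 2 1 2
F6 mo 0 0 2 0 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 1
F6 c1 fa mo 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F6 c2 fa mo 2 0 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F6 c3 fa mo 1 0 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2 1 2 1 2 1 2 1 1 1 2 1 2 1 2
F6 c4 fa mo 2 0 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1
F6 c5 fa mo 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 1 2 1 2 1 2 1 1 1 1 1 1 1 1 1 1 1 1
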