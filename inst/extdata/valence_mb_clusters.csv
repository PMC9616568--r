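valence,C1,C2,C3,C4,C5,C6,C7,C8,C9,C10
attractive,0,4,0,1,0,5,4,11,11,8
aversive,1,2,0,0,4,12,9,8,8,3
unknown,4,7,8,5,6,5,1,2,3,3
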