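homotype,valence
DA1,attractive
DA3,attractive
DL3,attractive
DM1,attractive
DM4,attractive
VA1v,attractive
VA2,attractive
VA3,attractive
VC1,attractive
VC2,attractive
VM1,attractive
VM2,attractive
VM4,attractive
VM5d,attractive
VM5v,attractive
VM7d,attractive
VM7v,attractive
D,aversive
DA2,aversive
DA4l,aversive
DA4m,aversive
DC1,aversive
DC2,aversive
DC3,aversive
DC4,aversive
DL1,aversive
DL4,aversive
DL5,aversive
DM2,aversive
DM3,aversive
DM5,aversive
DM6,aversive
DP1m,aversive
V,aversive
VA5,aversive
VA6,aversive
VA7l,aversive
VA7m,aversive
VC3,aversive
VL2a,aversive
VL2p,aversive
VM3,aversive
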