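from,to
Fp1,Fp2
Fp1,F3
Fp1,F7
Fp1,Fz
Fp2,F4
Fp2,F8
Fp2,Fz
F3,F7
F3,Fz
F3,FC1
F3,FC5
F4,F8
F4,Fz
F4,FC2
F4,FC6
C3,T7
C3,Cz
C3,FC1
C3,CP1
C3,FC5
C3,CP5
C4,T8
C4,Cz
C4,FC2
C4,CP2
C4,FC6
C4,CP6
P3,O1
P3,P7
P3,Pz
P3,CP1
P3,CP5
P4,O2
P4,P8
P4,Pz
P4,CP2
P4,CP6
O1,O2
O1,P7
O1,Pz
O2,P8
O2,Pz
F7,T7
F7,FC5
F8,T8
F8,FC6
T7,FC5
T7,CP5
T7,TP9
T8,FC6
T8,CP6
T8,TP10
P7,CP5
P7,TP9
P8,CP6
P8,TP10
Fz,Cz
Fz,FC1
Fz,FC2
Cz,Pz
Cz,FC1
Cz,FC2
Cz,CP1
Cz,CP2
Pz,CP1
Pz,CP2
FC1,FC5
FC2,FC6
CP1,CP5
CP2,CP6
CP5,TP9
CP6,TP10
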