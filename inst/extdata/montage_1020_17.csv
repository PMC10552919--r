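name,x,y,z
Fp1,-0.309017,0.951057,0
Fp2,0.309017,0.951057,0
F7,-0.809017,0.587785,0
F3,-0.480804,0.769563,0.420238
Fz,0,0.707107,0.707107
F4,0.480804,0.769563,0.420238
F8,0.809017,0.587785,0
T7,-1,0,0
C3,-0.707107,0,0.707107
Cz,0,0,1
C4,0.707107,0,0.707107
T8,1,0,0
P7,-0.809017,-0.587785,0
P3,-0.480804,-0.769563,0.420238
Pz,0,-0.707107,0.707107
P4,0.480804,-0.769563,0.420238
P8,0.809017,-0.587785,0
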