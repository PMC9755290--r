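label,x,y,z
Fp1,-27.185,83.667,28.584
Fp2,27.185,83.667,28.584
F7,-71.171,51.709,28.584
F3,-40.055,59.701,58.203
Fz,0,54.37,74.834
F4,40.055,59.701,58.203
F8,71.171,51.709,28.584
T3,-87.973,0,28.584
C3,-54.37,0,74.834
Cz,0,0,92.5
C4,54.37,0,74.834
T4,87.973,0,28.584
T5,-71.171,-51.709,28.584
P3,-40.055,-59.701,58.203
Pz,0,-54.37,74.834
P4,40.055,-59.701,58.203
T6,71.171,-51.709,28.584
O1,-27.185,-83.667,28.584
O2,27.185,-83.667,28.584
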