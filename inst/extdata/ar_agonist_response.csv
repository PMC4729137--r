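construct,hydroxyflutamide,bicalutamide,enzalutamide,arn509,source
WT,No,Partial,No,No,text
L702H,Partial,Partial,No,No,table
V716M,Partial,Partial,No,No,table
V731M,Partial,Partial,No,No,table
W742L,Partial,Yes,No,No,table
W742C,Partial,Yes,No,No,table
H875Y,Yes,Partial,Partial,Partial,table
H875Q,Partial,Partial,No,No,table
F877L,Partial,No,Partial,Partial,table
T878A,Partial,Yes,Partial,Partial,table
T878S,Partial,Yes,Partial,Partial,table
D880E,Partial,Partial,No,No,table
L882I,Partial,Partial,No,No,table
S889G,Yes,Yes,No,No,table
D891H,Yes,Yes,No,No,table
E894K,Partial,Partial,No,No,table
M896V,Partial,Yes,No,No,table
M896T,Partial,Yes,No,No,table
E898G,Partial,No,No,No,table
T919S,Partial,Partial,No,No,table
H875Q/T919S,Partial,Partial,No,No,table
T878A/S889G,Yes,Yes,Partial,Partial,table
T878A/D891H,Yes,Yes,Partial,No,table
F877L/T878A,No,Yes,Yes,Yes,table
H875Y/T878A,Yes,Yes,Partial,Partial,table
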