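construct,vpc13566_ic50_uM,dht_ec50_nM,estradiol_ec50_nM,progesterone_ec50_nM,hydrocortisone_ec50_nM
WT,1.73,0.05,>500,104.0,>500
L702H,6.13,8.00,>500,172.0,25.0
V716M,1.06,0.14,>500,329.0,>500
V731M,0.99,0.09,>500,115.0,>500
W742L,2.29,33.60,>500,>500,>500
W742C,3.43,4.74,>500,293.0,>500
H875Y,1.34,0.14,68.0,10.20,>500
H875Q,0.79,0.43,>500,>500,>500
F877L,0.37,0.08,>500,>500,>500
T878A,2.56,0.06,144.0,0.57,>500
T878S,0.43,0.02,100.0,0.53,>500
D880E,1.14,0.11,>500,177.0,>500
L882I,0.84,0.20,>500,>500,>500
S889G,10.48,0.37,230.0,17.20,>500
D891H,2.35,0.12,173.0,31.0,>500
E894K,1.20,0.25,>500,143.0,>500
M896V,0.59,4.50,>500,>500,>500
M896T,0.10,>500,>500,>500,>500
E898G,1.24,0.45,>500,>500,>500
T919S,1.29,0.03,>500,123.0,>500
H875Q/T919S,0.63,0.18,>500,>500,>500
T878A/S889G,13.20,0.12,94.0,0.36,>500
T878A/D891H,13.40,0.40,100.0,0.49,>500
H875Y/T878A,10.80,1.26,63.0,0.66,105.0
F877L/T878A,11.70,0.81,>500,5.70,>500
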