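symbol,atomic_number,atomic_mass,i_ev
H,1,1.008,19.2
C,6,12.011,81
N,7,14.007,82
O,8,15.999,106
Na,11,22.990,149
P,15,30.974,173
S,16,32.06,180
Ca,20,40.078,191
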