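element,atomic_mass_u,density_g_cm3
H,1.008,0.00008988
C,12.011,2.267
N,14.007,0.0012506
O,15.999,0.0014290
Na,22.990,0.971
Mg,24.305,1.738
P,30.974,1.823
S,32.06,2.067
Cl,35.45,0.0032
K,39.098,0.862
Ca,40.078,1.55
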