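tissue,density_g_cm3,element,mass_fraction
water,1.000,H,0.1119
water,1.000,O,0.8881
adipose,0.950,H,0.114
adipose,0.950,C,0.598
adipose,0.950,N,0.007
adipose,0.950,O,0.278
adipose,0.950,Na,0.001
adipose,0.950,S,0.001
adipose,0.950,Cl,0.001
soft_tissue,1.050,H,0.105
soft_tissue,1.050,C,0.256
soft_tissue,1.050,N,0.027
soft_tissue,1.050,O,0.602
soft_tissue,1.050,Na,0.001
soft_tissue,1.050,P,0.002
soft_tissue,1.050,S,0.003
soft_tissue,1.050,Cl,0.002
soft_tissue,1.050,K,0.002
mandible,1.680,H,0.046
mandible,1.680,C,0.199
mandible,1.680,N,0.041
mandible,1.680,O,0.435
mandible,1.680,Na,0.001
mandible,1.680,Mg,0.002
mandible,1.680,P,0.086
mandible,1.680,S,0.003
mandible,1.680,Ca,0.187
cortical_bone,1.920,H,0.034
cortical_bone,1.920,C,0.155
cortical_bone,1.920,N,0.042
cortical_bone,1.920,O,0.435
cortical_bone,1.920,Na,0.001
cortical_bone,1.920,Mg,0.002
cortical_bone,1.920,P,0.103
cortical_bone,1.920,S,0.003
cortical_bone,1.920,Ca,0.225
enamel,2.890,Ca,0.3989
enamel,2.890,P,0.1850
enamel,2.890,O,0.4141
enamel,2.890,H,0.0020
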