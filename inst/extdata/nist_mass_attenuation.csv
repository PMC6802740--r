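element,energy_kev,mu_over_rho_cm2_g
H,20,0.3695
H,30,0.3570
H,40,0.3458
H,50,0.3355
H,60,0.3260
H,80,0.3091
H,100,0.2944
H,150,0.2651
C,20,0.4420
C,30,0.2562
C,40,0.2076
C,50,0.1871
C,60,0.1753
C,80,0.1610
C,100,0.1514
C,150,0.1347
N,20,0.5952
N,30,0.3066
N,40,0.2288
N,50,0.1980
N,60,0.1817
N,80,0.1639
N,100,0.1529
N,150,0.1353
O,20,0.8651
O,30,0.3779
O,40,0.2585
O,50,0.2132
O,60,0.1907
O,80,0.1678
O,100,0.1551
O,150,0.1361
Na,20,1.665
Na,30,0.6100
Na,40,0.3507
Na,50,0.2559
Na,60,0.2126
Na,80,0.1735
Na,100,0.1546
Na,150,0.1319
Mg,20,2.266
Mg,30,0.7992
Mg,40,0.4358
Mg,50,0.3044
Mg,60,0.2463
Mg,80,0.1937
Mg,100,0.1688
Mg,150,0.1408
P,20,4.041
P,30,1.323
P,40,0.6655
P,50,0.4242
P,60,0.3223
P,80,0.2228
P,100,0.1845
P,150,0.1459
S,20,5.013
S,30,1.631
S,40,0.8098
S,50,0.5066
S,60,0.3780
S,80,0.2524
S,100,0.2030
S,150,0.1550
Cl,20,5.725
Cl,30,1.843
Cl,40,0.9076
Cl,50,0.5590
Cl,60,0.4106
Cl,80,0.2661
Cl,100,0.2107
Cl,150,0.1573
K,20,8.679
K,30,2.745
K,40,1.331
K,50,0.7976
K,60,0.5678
K,80,0.3428
K,100,0.2586
K,150,0.1790
Ca,20,10.34
Ca,30,3.256
Ca,40,1.568
Ca,50,0.9324
Ca,60,0.6578
Ca,80,0.3886
Ca,100,0.2884
Ca,150,0.1930
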