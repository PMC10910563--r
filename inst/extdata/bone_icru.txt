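# Mass attenuation coefficients for ICRU cortical bone (cm^2/g), transcribed
# from the NIST standard compilation; sub-10 keV rows are smooth photoelectric
# extrapolations (no filtered beam carries flux there). Nominal density
# 1.85 g/cm^3 in this package.
energy_kev	mu_over_rho
1	26000
1.5	8000
2	3400
3	1030
4	443
5	228
6	132.2
8	55.7
10	28.51
15	9.032
20	4.001
30	1.331
40	0.6655
50	0.4242
60	0.3148
80	0.2229
100	0.1855
150	0.1480
200	0.1309
300	0.1113
400	0.09908
500	0.09022
800	0.07308
1000	0.06566
1500	0.05346
2000	0.04607
3000	0.03745
4000	0.03283
5000	0.02990
6000	0.02789
8000	0.02530
10000	0.02387
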