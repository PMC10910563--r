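# Mass attenuation coefficients for ICRU-44 soft tissue (cm^2/g), transcribed
# from the NIST standard compilation; sub-4 keV rows are smooth photoelectric
# extrapolations. Nominal density 1.00 g/cm^3 in this package.
energy_kev	mu_over_rho
1	4107
1.5	1386
2	621.9
3	194.3
4	83.38
5	42.89
6	24.82
8	10.45
10	5.367
15	1.693
20	0.8205
30	0.3783
40	0.2688
50	0.2264
60	0.2048
80	0.1823
100	0.1693
200	0.1358
300	0.1175
400	0.1051
500	0.09593
800	0.07789
1000	0.07003
1500	0.05699
2000	0.04893
3000	0.03929
4000	0.03367
5000	0.02998
6000	0.02739
8000	0.02400
10000	0.02191
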