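# Mass attenuation coefficients for elemental aluminum (cm^2/g), transcribed
# from the NIST standard compilation, including the K edge at 1.560 keV.
# Nominal density 2.699 g/cm^3. Used for tube filtration.
energy_kev	mu_over_rho
1	1185
1.56	402.2
1.5601	3957
2	2263
3	788.0
4	360.5
5	193.4
6	115.3
8	50.33
10	26.23
15	7.955
20	3.441
30	1.128
40	0.5685
50	0.3681
60	0.2778
80	0.2018
100	0.1704
200	0.1223
300	0.1042
400	0.09276
500	0.08445
800	0.06841
1000	0.06146
1500	0.05006
2000	0.04324
3000	0.03541
4000	0.03106
5000	0.02836
6000	0.02655
8000	0.02437
10000	0.02318
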