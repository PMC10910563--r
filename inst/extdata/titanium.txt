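# Mass attenuation coefficients for elemental titanium (cm^2/g), transcribed
# from the NIST standard compilation, including the K edge at 4.966 keV.
# Nominal density 4.506 g/cm^3 (commercially pure implant grade).
energy_kev	mu_over_rho
1	5869
1.5	2096
2	986.0
3	332.3
4	151.7
4.966	83.80
4.9661	687.8
5	683.8
6	432.3
8	202.3
10	110.7
15	35.87
20	15.85
30	4.972
40	2.214
50	1.213
60	0.7661
80	0.4052
100	0.2721
200	0.1314
300	0.1043
400	0.09081
500	0.08191
800	0.06572
1000	0.05891
1500	0.04801
2000	0.04180
3000	0.03512
4000	0.03173
5000	0.02982
6000	0.02868
8000	0.02759
10000	0.02727
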