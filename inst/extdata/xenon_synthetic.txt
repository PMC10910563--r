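# SYNTHETIC mass attenuation table for xenon (cm^2/g), used only to shape the
# default detective-efficiency model of the high-DQE pressurised-xenon
# detector. Constructed from Klein-Nishina Compton scattering (Z/A = 0.411)
# plus fitted photoelectric and pair-production terms with the K edge at
# 34.56 keV; the MeV tail is flattened to a monotone effective-efficiency
# model. Not a NIST transcription. Nominal density 5.9e-3 g/cm^3 (the detector
# model works in calibrated mass thickness, so density is not load-bearing).
energy_kev	mu_over_rho
1	40000
1.5	15000
2	8000
3	3000
4	1400
5	900
6	560
8	250
10	130
15	42
20	19.0
30	6.30
34.56	4.30
34.561	23.5
40	16.0
50	9.10
60	5.65
80	2.64
100	1.51
200	0.300
300	0.148
400	0.105
500	0.0857
800	0.0630
1000	0.0550
1500	0.0445
2000	0.0396
3000	0.0355
4000	0.0340
5000	0.0337
6000	0.0336
8000	0.0336
10000	0.0336
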