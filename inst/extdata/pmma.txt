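# Mass attenuation coefficients for PMMA (cm^2/g), transcribed from the NIST
# standard compilation; sub-10 keV rows smoothed. Nominal density 1.19 g/cm^3.
energy_kev	mu_over_rho
1	2794
1.5	917
2	413.7
3	121.4
4	51.06
5	25.90
6	14.82
8	6.30
10	3.357
15	1.101
20	0.5714
30	0.3032
40	0.2350
50	0.2074
60	0.1924
80	0.1751
100	0.1641
200	0.1328
300	0.1152
400	0.1031
500	0.09410
800	0.07641
1000	0.06870
1500	0.05591
2000	0.04796
3000	0.03844
4000	0.03286
5000	0.02919
6000	0.02658
8000	0.02317
10000	0.02105
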