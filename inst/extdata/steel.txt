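# Mass attenuation coefficients for surgical stainless steel (cm^2/g).
# Austenitic implant steel is iron-dominated (Cr and Ni are adjacent in Z and
# contribute near-identical per-gram coefficients), so the elemental iron table
# from the NIST standard compilation is used, including the Fe K edge at
# 7.112 keV. Nominal density 8.0 g/cm^3 (316L).
energy_kev	mu_over_rho
1	9085
1.5	3399
2	1626
3	557.6
4	256.7
5	139.8
6	84.84
7.112	53.19
7.1121	407.6
8	305.6
10	170.6
15	57.08
20	25.68
30	8.176
40	3.629
50	1.958
60	1.205
80	0.5952
100	0.3717
200	0.1460
300	0.1099
400	0.09400
500	0.08414
800	0.06699
1000	0.05995
1500	0.04883
2000	0.04265
3000	0.03621
4000	0.03312
5000	0.03146
6000	0.03057
8000	0.02991
10000	0.02994
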