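# Independent reference values from the NIST standard compilation at energies
# deliberately held out of the packaged tables (150, 600, 1250 keV), used to
# check the package's log-log interpolation against an external lookup.
material	energy_kev	mu_over_rho
water	150	0.1505
water	600	0.08956
water	1250	0.06323
tissue	150	0.1492
tissue	600	0.08870
tissue	1250	0.06262
bone	600	0.08332
bone	1250	0.05871
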