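wavelength_nm,mu_a_cm
700,0.00624
725,0.01600
750,0.02816
775,0.02407
800,0.02241
825,0.02863
850,0.04332
875,0.05237
900,0.06791
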