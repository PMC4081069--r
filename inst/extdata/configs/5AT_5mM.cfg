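# 5'AT: 64 bp AT-rich duplex, one end sealed. Low salt (5 mM NaCl): melting
# and rezip forces are both reduced, melting more strongly.
construct = FIVE_PRIME_AT
salt = LOW_5MM
duplex_bp = 64
segments = at_core:64:AT_RICH
linker_config = ONE_END
scheme = peeling

ds_rise_nm = 0.34
ds_persistence_nm = 50
ds_stretch_modulus_pN = 1200
ss_persistence_nm = 0.75
ss_stretch_modulus_pN = 800
handle_contour_nm = 120

melt_force_pN = 43.6
melt_force_sd_pN = 2.79
rezip_force_pN = 17.3
rezip_force_sd_pN = 0.98
# peeled-strand elasticity taken identical to high salt (calibrated at the
# high-salt melt); only the kinetics carry the salt dependence
calib_force_pN = 61.5
calib_extension_nm = 14.7

# order-of-magnitude defaults (intermediate hopping not quantified)
hop_midpoint_pN = 42.5
hop_extension_nm = 4.0
hop_attempt_rate_hz = 20
hop_peel_bp = 18

loading_rate_pN_s = 7.8
noise_sd_pN = 0.3
force_min_pN = 10
force_max_pN = 55
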