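# 5'AT: 64 bp AT-rich duplex, one end sealed by an inter-strand cross-link.
# High salt (1 M NaCl). Peeling: abrupt melt rip on pull, hysteretic rezip.
construct = FIVE_PRIME_AT
salt = HIGH_1M
duplex_bp = 64
segments = at_core:64:AT_RICH
linker_config = ONE_END
scheme = peeling

# elasticity (worm-like chains; ss contour per nt is calibrated at load time
# against calib_extension_nm at calib_force_pN)
ds_rise_nm = 0.34
ds_persistence_nm = 50
ds_stretch_modulus_pN = 1200
ss_persistence_nm = 0.75
ss_stretch_modulus_pN = 800
handle_contour_nm = 120

# measured ensemble targets (mean +/- 1 s.d.) the kinetics are calibrated to
melt_force_pN = 61.5
melt_force_sd_pN = 2.62
rezip_force_pN = 21.7
rezip_force_sd_pN = 1.27
calib_force_pN = 61.5
calib_extension_nm = 14.7

# partial-peel bistable intermediate. These rates/positions are
# order-of-magnitude choices: the hopping kinetics of the intermediate are not
# experimentally quantified, only its existence, its attachment to the B-form
# branch and its rough position below the melt rip.
hop_midpoint_pN = 60.5
hop_extension_nm = 4.0
hop_attempt_rate_hz = 20
hop_peel_bp = 18

loading_rate_pN_s = 7.8
noise_sd_pN = 0.3
force_min_pN = 15
force_max_pN = 70
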