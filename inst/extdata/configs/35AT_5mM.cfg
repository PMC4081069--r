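# 3'5'AT: 64 bp AT-rich duplex sealed at both ends. Low salt (5 mM NaCl):
# melts in a single abrupt step and rehybridizes hysteretically in one step.
construct = THREE_FIVE_PRIME_AT
salt = LOW_5MM
duplex_bp = 64
segments = at_core:64:AT_RICH
linker_config = BOTH_ENDS
scheme = two_state_rupture

ds_rise_nm = 0.34
ds_persistence_nm = 50
ds_stretch_modulus_pN = 1200
ss_persistence_nm = 0.75
ss_stretch_modulus_pN = 800
handle_contour_nm = 120

melt_force_pN = 61.0
melt_force_sd_pN = 2.27
rezip_force_pN = 41.1
rezip_force_sd_pN = 4.88
calib_force_pN = 61.0
calib_extension_nm = 9.30
hysteretic_probability = 1.0

loading_rate_pN_s = 7.8
noise_sd_pN = 0.3
force_min_pN = 25
force_max_pN = 70
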