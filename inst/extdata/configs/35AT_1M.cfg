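# 3'5'AT: 64 bp AT-rich duplex sealed at both ends. High salt (1 M NaCl).
# Internal (bubble) melting: gradual non-cooperative two-state transition with
# no rips; about 22% of relax curves instead follow a hysteretic pathway that
# returns to the B-form in one abrupt step.
construct = THREE_FIVE_PRIME_AT
salt = HIGH_1M
duplex_bp = 64
segments = at_core:64:AT_RICH
linker_config = BOTH_ENDS
scheme = internal_eq

ds_rise_nm = 0.34
ds_persistence_nm = 50
ds_stretch_modulus_pN = 1200
ss_persistence_nm = 0.75
ss_stretch_modulus_pN = 800
handle_contour_nm = 120

# equilibrium two-state transition: midpoint force and cooperative length
ftr_pN = 67.8
delta_nm = 2.6
calib_force_pN = 67.8
calib_extension_nm = 10.6

# hysteretic relax pathway: probability from the observed 34 / 155 relax
# curves; the abrupt rezip force of that pathway is not printed - 45 pN is an
# order-of-magnitude choice below the 60-70 pN transition region
hysteretic_probability = 0.21935484
hyst_rezip_force_pN = 45
hyst_rezip_force_sd_pN = 1.3

loading_rate_pN_s = 7.8
noise_sd_pN = 0.3
force_min_pN = 30
force_max_pN = 76
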