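# ATGC: 122 bp composite duplex - 60 bp AT-rich core next to a 62 bp GC-rich
# part (sealed in the GC end). High salt (1 M NaCl): reversible AT peeling
# (bistable) followed by a reversible, bistable B-to-S transition in the GC
# part; modeled as a three-state ladder B <-> I <-> S.
construct = ATGC
salt = HIGH_1M
duplex_bp = 122
segments = at_core:60:AT_RICH,gc_part:62:GC_RICH
linker_config = ONE_END
scheme = composite

ds_rise_nm = 0.34
ds_persistence_nm = 50
ds_stretch_modulus_pN = 1200
ss_persistence_nm = 0.75
ss_stretch_modulus_pN = 800
sform_persistence_nm = 15
sform_stretch_modulus_pN = 1500
handle_contour_nm = 120

# three-state populations: B/I crossing at ftr1, intermediate-population
# maximum at ftr; the I/S crossing force follows from these and the transition
# distances dx1 (B->I) and dx2 (I->S)
ftr1_pN = 62.1
ftr_pN = 64.3
dx1_nm = 8.0
dx2_nm = 11.9
# the intermediate is a composite (split) state: its branch gains an extra
# intermediate_extra_nm of extension between the two crossing forces, giving
# it a smaller force-position gradient than the flanking branches
intermediate_extra_nm = 4.8
hop_attempt_rate_hz = 40
n_peel_bp = 60
calib_force_pN = 62.1
calib_extension_nm = 8.0
calib_total_extension_nm = 24.7

loading_rate_pN_s = 7.8
noise_sd_pN = 0.3
force_min_pN = 50
force_max_pN = 72
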