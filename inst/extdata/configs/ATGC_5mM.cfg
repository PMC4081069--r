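# ATGC: 122 bp composite duplex. Low salt (5 mM NaCl): the AT melting splits
# into two reversible sub-steps (t1, t2), followed by the B-to-S transition of
# the GC part (t3) and an irreversible full-melt channel at higher force with
# hysteretic rezipping near 20 pN.
construct = ATGC
salt = LOW_5MM
duplex_bp = 122
segments = at_core:60:AT_RICH,gc_part:62:GC_RICH
linker_config = ONE_END
scheme = composite_low

ds_rise_nm = 0.34
ds_persistence_nm = 50
ds_stretch_modulus_pN = 1200
ss_persistence_nm = 0.75
ss_stretch_modulus_pN = 800
sform_persistence_nm = 15
sform_stretch_modulus_pN = 1500
handle_contour_nm = 120

t1_pN = 45
t2_pN = 49
t3_pN = 59
dx1_nm = 4.0
dx2_nm = 4.0
dx3_nm = 11.9
hop_attempt_rate_hz = 40
n_peel_bp = 60
calib_force_pN = 49
calib_extension_nm = 8.0

# irreversible full melt above the B-to-S transition (channel c.); the extra
# extension of the fully molten state over S is an order-of-magnitude choice
melt_force_pN = 64
melt_force_sd_pN = 2.0
rezip_force_pN = 20
rezip_force_sd_pN = 1.5
full_melt_extra_nm = 6.0

loading_rate_pN_s = 7.8
noise_sd_pN = 0.3
force_min_pN = 15
force_max_pN = 70
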