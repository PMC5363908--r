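global_threshold = 60
otsu_enabled = true
window_width_um = 500
window_depth_um = 350
ap_extent_um = 750
profile_band_um = 750
plate_bvf_cutoff = 0.9
boundary_consecutive = 1
morph_radius_um = 10
gaussian_sigma = 2
osteophyte_voi_fraction = 0.333333333333333
centre_offset_fraction = 0.25
thickness_agg = "mean"
bmd_bone_only = true
random_seed = 1
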