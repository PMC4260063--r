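# Demo pipeline configuration: synthetic scenario at the pilot scale
# (~2666 users over a 132.4 sq mi region, k = 50, 2-mile max radius,
# 2-mile gaussian smoothing).
seed: 1
n_total: 2666
k: 50
r_max_mi: 2.0
bandwidth_mi: 2.0
cell_size_mi: 0.1
kernel: gaussian
n_sd: 2
weight_mode: standardized
p_missing_race: 0.0551
p_missing_age: 0.2224
out_dir: appdens-out
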