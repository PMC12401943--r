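# Default desk-scale study configuration for run_study() /
# `dfsct reproduce-study --config`.
geometries: [VCT40, VCT140, DFSSD]
protocols: [axial_half, helical_0.5, helical_0.75, helical_1.0]
scale: 0.25
nx: 256
seed: 17
photons_per_mas: 2.0e5
noise: yes
supersample: 2
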