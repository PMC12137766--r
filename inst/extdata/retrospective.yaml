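# Retrospectively distortion-matched whole-brain protocol
# (IR timings and flip angle as printed; echo spacing and shots per TI
# block are representative values, see package documentation)
ti1: 930
ti2: 2368
te: 8
tr_shot: 23
tr_ir: 3097
fa1: 10
fa2: 10
n_segments: 14
matrix_size: [232, 232, 186]
partial_fourier: 0.75
caipi_dz: 3
r_inplane: 1
echo_spacing: 1.05
inversion_efficiency: 1.0
shots_per_ti_block: 27
voxel_size: [0.8, 0.8, 0.8]
tag: retrospective
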