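# Acquisition distortion-matched protocol, configured for an effective
# echo spacing of 0.35 ms (echo_spacing / (n_segments * r_inplane))
ti1: 1378
ti2: 3793
te: 26
tr_shot: 78
tr_ir: 5050
fa1: 10
fa2: 10
n_segments: 3
matrix_size: [232, 232, 186]
partial_fourier: 0.75
caipi_dz: 3
r_inplane: 1
echo_spacing: 1.05
inversion_efficiency: 1.0
shots_per_ti_block: 10
voxel_size: [0.8, 0.8, 0.8]
tag: acquisition_matched
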