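gait_sample
version=1
seed=0
model=planar_fixture
nRows=5
nColumns=4
inDegrees=no
endheader
time	knee_r	ankle_r	grf_vy_r
0	-0.0873	0	0
0.2	-0.28	0.035	608.5
0.4	-0.12	0.122	455.25
0.6	-1.0472	-0.2967	62
0.8	-0.17	0.07	0
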