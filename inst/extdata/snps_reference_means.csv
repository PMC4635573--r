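variety,model,true_mean,est_mean,printed_deviation_pct
A,area_20,93.3,92.4,-0.96
A,tlpb2_image_20,93.3,93.3,0
A,tlpb2_manual,96.1,96.8,0.73
A,area_cal,88.7,88.7,0
A,tlpb2_cal,88.7,90.2,1.69
B,area_20,116.5,115.5,0.86
B,tlpb2_image_20,116.5,116.3,0.17
B,tlpb2_manual,111.0,110.7,0.27
B,area_cal,108.8,110.3,1.38
B,tlpb2_cal,108.8,110.0,1.10
C,area_20,105.9,107.1,1.13
C,tlpb2_image_20,105.9,105.6,0.28
C,tlpb2_manual,106.1,106.4,0.28
C,area_cal,112.9,112.9,0
C,tlpb2_cal,112.9,112.8,-0.09
D,area_20,90.0,89.6,-0.44
D,tlpb2_image_20,90.0,90.4,0.44
D,tlpb2_manual,99.2,99.0,-0.20
D,area_cal,89.4,90.6,1.34
D,tlpb2_cal,89.4,89.9,0.56
E,area_20,185.2,185.0,-0.11
E,tlpb2_image_20,185.2,186.8,0.86
E,tlpb2_manual,207.2,212.8,2.70
E,area_cal,182.3,184.2,1.04
E,tlpb2_cal,182.3,186.1,2.08
F,area_20,203.2,203.0,-0.10
F,tlpb2_image_20,203.2,198.2,-2.46
F,tlpb2_manual,197.2,204.0,3.45
F,area_cal,206.4,206.8,0.19
F,tlpb2_cal,206.4,206.9,0.24
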