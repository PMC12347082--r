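parameter,dental_maxilla,dental_mandible,bony_mandible
pitch,42.31,57.69,26.92
roll,0.00,15.38,3.85
yaw,3.85,26.92,15.38
mean_rotations,15.39,33.33,15.38
trans_LR,11.54,50.00,26.92
trans_AP,23.08,50.00,15.38
trans_UD,30.77,34.62,11.54
mean_translations,21.80,44.87,17.95
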