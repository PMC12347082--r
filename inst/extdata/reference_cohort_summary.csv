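segment,parameter,mean,sem,top10_value,ci_low,ci_high,p_printed
dental_maxilla,pitch,-2.85,0.68,7.47,-4.25,-1.44,<0.001
dental_maxilla,roll,0.05,0.21,1.47,-0.39,0.49,0.804
dental_maxilla,yaw,-0.54,0.33,2.19,-1.23,0.14,0.114
dental_maxilla,trans_LR,0.34,0.21,1.75,-0.10,0.79,0.120
dental_maxilla,trans_AP,-0.74,0.54,4.44,-1.84,0.37,0.181
dental_maxilla,trans_UD,-0.82,0.41,2.89,-0.03,1.67,0.059
dental_mandible,pitch,-1.63,1.30,9.75,-4.31,1.05,0.222
dental_mandible,roll,0.51,0.72,5.51,-0.98,2.00,0.485
dental_mandible,yaw,-1.52,0.92,7.54,-3.41,0.38,0.111
dental_mandible,trans_LR,1.19,0.51,4.49,0.15,2.24,0.027
dental_mandible,trans_AP,0.72,0.45,3.70,-0.21,1.64,0.124
dental_mandible,trans_UD,0.02,0.51,3.88,-1.03,1.07,0.970
bony_mandible,pitch,-0.41,0.71,5.88,-1.87,1.05,0.566
bony_mandible,roll,0.31,0.39,2.56,-0.49,1.11,0.430
bony_mandible,yaw,-1.21,0.49,5.06,-2.23,-0.20,0.121
bony_mandible,trans_LR,0.76,0.37,3.45,0.00,1.52,0.052
bony_mandible,trans_AP,0.12,0.28,2.38,-0.46,0.70,0.674
bony_mandible,trans_UD,0.08,0.27,1.99,-0.48,0.63,0.777
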