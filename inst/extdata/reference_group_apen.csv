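electrode,condition,mean_vs,sd_vs,mean_mcs,sd_mcs,F,p
FP1,resting,0.60,0.14,0.72,0.18,9.96,0.002
FP2,resting,0.61,0.17,0.65,0.17,0.96,0.332
F3,resting,0.68,0.19,0.78,0.24,5.08,0.027
F4,resting,0.66,0.15,0.74,0.21,3.50,0.066
C3,resting,0.62,0.18,0.77,0.24,10.22,0.002
C4,resting,0.68,0.17,0.75,0.20,2.33,0.131
P3,resting,0.67,0.19,0.79,0.19,7.62,0.007
P4,resting,0.64,0.19,0.71,0.22,2.35,0.129
O1,resting,0.67,0.18,0.74,0.19,2.93,0.091
O2,resting,0.67,0.18,0.75,0.20,0.07,0.066
F7,resting,0.62,0.21,0.72,0.21,4.36,0.040
F8,resting,0.70,0.19,0.75,0.19,1.64,0.205
T3,resting,0.66,0.20,0.76,0.20,4.41,0.039
T4,resting,0.70,0.18,0.73,0.23,0.58,0.450
T5,resting,0.64,0.19,0.75,0.20,5.90,0.018
T6,resting,0.71,0.19,0.74,0.22,0.25,0.617
FP1,music,0.59,0.17,0.77,0.18,18.92,0.0005
FP2,music,0.64,0.18,0.66,0.18,0.43,0.516
F3,music,0.70,0.22,0.82,0.24,5.89,0.018
F4,music,0.68,0.18,0.75,0.18,3.01,0.087
C3,music,0.62,0.17,0.81,0.24,15.93,0.0005
C4,music,0.70,0.16,0.76,0.18,2.67,0.107
P3,music,0.68,0.17,0.82,0.18,11.96,0.001
P4,music,0.66,0.21,0.73,0.22,2.36,0.129
O1,music,0.67,0.18,0.78,0.20,6.13,0.016
O2,music,0.70,0.19,0.78,0.19,2.89,0.093
F7,music,0.63,0.22,0.77,0.22,7.27,0.009
F8,music,0.71,0.19,0.78,0.19,2.62,0.110
T3,music,0.66,0.20,0.79,0.18,8.44,0.005
T4,music,0.72,0.19,0.78,0.22,1.94,0.168
T5,music,0.66,0.20,0.78,0.19,7.87,0.006
T6,music,0.73,0.19,0.78,0.16,1.78,0.187
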