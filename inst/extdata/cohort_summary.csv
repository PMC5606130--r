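subject,usable_electrodes,scored_epochs,kappa_leave_one_out,kappa_total,kappa_individual
1,10,1040,0.05,0.50,0.52
2,10,964,0.36,0.49,0.52
3,11,932,0.57,0.63,0.67
4,12,1150,0.60,0.65,0.72
5,6,491,0.03,0.57,0.55
6,12,926,0.59,0.64,0.65
7,12,758,0.75,0.78,0.76
8,11,293,0.65,0.65,0.70
9,10,857,0.44,0.70,0.76
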