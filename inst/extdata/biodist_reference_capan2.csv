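organ,time_h,mean,sd
tumor,24,3.13,0.63
tumor,48,2.45,0.39
tumor,72,3.46,0.85
tumor,192,1.16,0.21
small intestine,24,0.76,0.17
small intestine,48,0.35,0.08
small intestine,72,0.27,0.10
small intestine,192,0.02,0.00
colon,24,1.37,0.36
colon,48,0.56,0.06
colon,72,0.43,0.21
colon,192,0.04,0.01
liver,24,0.24,0.03
liver,48,0.18,0.04
liver,72,0.20,0.04
liver,192,0.08,0.02
spleen,24,0.06,0.01
spleen,48,0.07,0.01
spleen,72,0.18,0.21
spleen,192,0.04,0.01
kidney,24,19.21,2.53
kidney,48,12.50,0.55
kidney,72,14.71,4.48
kidney,192,2.28,0.40
heart,24,0.16,0.03
heart,48,0.07,0.01
heart,72,0.08,0.04
heart,192,0.04,0.01
blood,24,0.01,0.00
blood,48,0.00,0.00
blood,72,0.01,0.00
blood,192,0.00,0.00
lung,24,1.74,0.46
lung,48,0.53,0.13
lung,72,0.52,0.13
lung,192,0.06,0.01
muscle,24,0.26,0.09
muscle,48,0.11,0.02
muscle,72,0.10,0.02
muscle,192,0.04,0.01
femur,24,0.30,0.04
femur,48,0.45,0.65
femur,72,0.13,0.03
femur,192,0.07,0.02
stomach,24,1.92,0.55
stomach,48,1.01,0.19
stomach,72,0.83,0.13
stomach,192,0.14,0.03
pancreas,24,0.65,0.98
pancreas,48,0.17,0.05
pancreas,72,0.29,0.26
pancreas,192,0.03,0.01
tail,24,0.31,0.05
tail,48,0.20,0.05
tail,72,0.16,0.03
tail,192,0.08,0.05
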