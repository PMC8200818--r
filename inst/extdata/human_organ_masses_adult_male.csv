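organ,mass_g
small intestine,677
colon,387
liver,1910
spleen,183
kidney,299
heart,316
lung,1000
muscle,28000
stomach,158
pancreas,94.3
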