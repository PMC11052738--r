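# Published time-integrated activity coefficients [MBq-h/MBq] for the same
# four-patient 99mTc GRPR-tracer cohort as example_effective_half_lives.csv.
organ,P1,P2,P3,P4
heart,0.029,0.016,0.019,0.012
kidneys,0.066,0.080,0.060,0.054
liver,0.062,0.056,0.078,0.056
lungs,0.032,0.016,NA,NA
pancreas,0.042,0.011,0.021,0.018
red_marrow,0.068,0.043,0.109,0.063
spleen,0.004,0.005,0.003,0.006
urinary_bladder,0.67,0.66,0.66,0.70
remainder,2.4,2.3,2.8,2.6
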