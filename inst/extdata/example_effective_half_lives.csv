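# Published effective half-lives [h] of a 99mTc-labelled GRPR-targeted
# tracer in a four-patient cohort; lungs were not assessed in P3/P4
# (indistinguishable from background) and are recorded as NA.
organ,P1,P2,P3,P4
heart,1.6,1.0,2.2,1.8
kidneys,2.7,1.1,3.2,3.3
liver,2.8,1.3,2.9,2.3
lungs,1.2,0.79,NA,NA
pancreas,1.1,0.82,0.79,1.1
red_marrow,2.7,1.7,6.0,4.4
spleen,2.5,0.93,1.9,2.7
whole_body,1.9,1.8,2.2,2.1
wb_minus_bladder,1.8,1.7,2.1,1.9
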