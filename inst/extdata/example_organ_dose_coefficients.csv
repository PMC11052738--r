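# Published cohort-mean organ absorbed-dose coefficients [mGy/MBq] for the
# four-patient 99mTc GRPR-tracer study (adult-male phantom, OLINDA-style
# MIRD computation with individual organ masses).
organ,mean_mGy_per_MBq,sd_mGy_per_MBq
adrenals,0.0018,0.0002
brain,0.0011,0.0002
breasts,0.0009,0.0001
gallbladder_wall,0.0018,0.0002
lli_wall,0.0030,0.0002
small_intestine,0.0022,0.0002
stomach_wall,0.0016,0.0002
uli_wall,0.0020,0.0002
heart_wall,0.0014,0.0002
kidneys,0.0034,0.0003
liver,0.0019,0.0004
lungs,0.0013,0.0003
muscle,0.0015,0.0002
pancreas,0.0043,0.0015
red_marrow,0.0015,0.0003
osteogenic_cells,0.0039,0.0005
skin,0.0009,0.0001
spleen,0.0016,0.0005
testes,0.0021,0.0002
thymus,0.0013,0.0002
thyroid,0.0013,0.0002
urinary_bladder_wall,0.0281,0.0008
total_body,0.0015,0.0002
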