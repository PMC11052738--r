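# Patient characteristics and injected activities for the four-patient
# 99mTc GRPR-tracer cohort.
patient_id,age_y,weight_kg,height_cm,injected_mbq
P1,70,84,170,683
P2,58,102,186,739
P3,66,85,172,836
P4,68,80,172,828
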