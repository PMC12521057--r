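category,body_region,dose_category,noise_threshold_hu
renal_stone,abdomen,low,64
abdomen_pelvis_wo,abdomen,routine,29
enterography,abdomen,routine,29
urogram,abdomen,high,29
renal_mass_wo,abdomen,high,29
chest_wo,chest,routine,49
pulmonary_embolism,chest,high,49
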