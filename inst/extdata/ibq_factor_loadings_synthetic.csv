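subscale,label,SUR,NEG,REG
ibq_01,approach,0.72,0,0
ibq_02,vocal_reactivity,0.65,0,0
ibq_03,high_intensity_pleasure,0.60,0,0
ibq_04,smiling_laughter,0.55,0,0
ibq_05,activity_level,0.50,0,0
ibq_06,perceptual_sensitivity,0.45,0,0
ibq_07,sadness,0,0.70,0
ibq_08,distress_to_limitations,0,0.65,0
ibq_09,fear,0,0.60,0
ibq_10,falling_reactivity,0,0.45,0
ibq_11,low_intensity_pleasure,0,0,0.70
ibq_12,cuddliness,0,0,0.65
ibq_13,duration_of_orienting,0,0,0.55
ibq_14,soothability,0,0,0.50
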