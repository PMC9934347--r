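subject,first_change_time_min,first_change_pressure_mmHg,end_time_min,end_pressure_mmHg
animal_1,22,25,72,51
animal_2,5,20,60,20
animal_3,25,22,80,40
animal_4,20,22,80,50
animal_5,5,16,60,54
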