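id,group,age,sex,height_cm,weight_kg,hr_baseline_max,hr_tilt_max,tilt_duration_min
POTS-1,POTS,14,F,175.7,58,76,123,30
POTS-2,POTS,13,F,157.5,41.1,76,123,30
POTS-3,POTS,16,F,168,63,76,123,30
POTS-4,POTS,15,F,159.9,75.3,76,123,30
POTS-5,POTS,11,M,149.9,44,76,123,30
POTS-6,POTS,16,F,167,51.6,76,123,30
control-1,control,22,M,170.6,64,66,85,30
control-2,control,21,M,173,65,66,85,30
control-3,control,18,F,145.3,51,66,85,30
control-4,control,22,F,158.9,60,66,85,30
control-5,control,21,F,155.4,55,66,85,30
control-6,control,23,M,182.8,63,66,85,30
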