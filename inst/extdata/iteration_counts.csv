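condition,iteration,present,absent,former,unknown,total
smoking,1,75,42,87,787,991
smoking,2,646,211,417,9854,11128
diabetes,1,279,29,,683,991
diabetes,2,257,37,,10834,11128
hypertension,1,217,8,,766,991
hypertension,2,1184,30,,9914,11128
heart_failure,1,46,41,,904,991
heart_failure,2,183,217,,10728,11128
copd,1,22,0,,969,991
copd,2,366,1,,10761,11128
family_cancer,1,5,0,,986,991
family_cancer,2,2,1,,11125,11128
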