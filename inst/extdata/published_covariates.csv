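parameter,mean,sd,low,high
male_age,34.99,4.46,26,44
semen_volume,3.69,1.62,0.5,8
ej_concentration,93.67,64.87,4,439
ej_total_count,315.27,233.75,12.5,1223
ej_progressive_motility,46.01,18.31,5,86
ej_immotile,32.07,19.6,1,86
ej_total_motile,164.52,159.72,2.5,819
ej_morphology,6.19,4.14,1,18
ej_alkaline_comet,47.04,12.88,22,82
ej_neutral_comet,56.21,17.05,23,91
su_concentration,85.7,69.99,1.19,395.95
su_total_count,34.85,28.11,0.48,158.38
su_progressive_motility,72.87,19.33,10,98
su_immotile,13.75,15.79,0,81
su_total_motile,25.27,21.72,0.26,125.12
su_alkaline_comet,42.27,11.92,20,75
su_neutral_comet,52.47,16.33,17,91
female_age,32.54,4.39,21,40
bmi,24.84,6.14,17.24,45
infertility_duration,25.64,19.74,5,120
fsh,6.73,1.74,1.58,11.4
lh,6.4,3.91,0.54,27.28
estradiol,52.3,47.65,6,450
prolactin,14.91,8.9,3.18,77.82
antral_follicle_count,14.01,6.85,3,30
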