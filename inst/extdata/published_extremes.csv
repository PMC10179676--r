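period,group,parameter,min,max,synthetic
discovery,no_pregnancy,male_age,26,44,FALSE
discovery,no_pregnancy,semen_volume,0.5,8,FALSE
discovery,no_pregnancy,ej_concentration,4,439,FALSE
discovery,no_pregnancy,ej_total_count,12.5,1223,FALSE
discovery,no_pregnancy,ej_progressive_motility,5,86,FALSE
discovery,no_pregnancy,ej_immotile,1,86,FALSE
discovery,no_pregnancy,ej_total_motile,2.5,819,FALSE
discovery,no_pregnancy,ej_morphology,1,18,FALSE
discovery,no_pregnancy,ej_alkaline_comet,22,82,FALSE
discovery,no_pregnancy,ej_neutral_comet,23,90,FALSE
discovery,no_pregnancy,su_concentration,1.19,267,FALSE
discovery,no_pregnancy,su_total_count,0.48,106.9,FALSE
discovery,no_pregnancy,su_progressive_motility,10,98,FALSE
discovery,no_pregnancy,su_immotile,0,81,FALSE
discovery,no_pregnancy,su_total_motile,0.26,90.6,FALSE
discovery,no_pregnancy,su_alkaline_comet,20,75,FALSE
discovery,no_pregnancy,su_neutral_comet,17,91,FALSE
discovery,pregnancy,male_age,26,41,FALSE
discovery,pregnancy,semen_volume,1.5,7.5,FALSE
discovery,pregnancy,ej_concentration,10.36,243.99,FALSE
discovery,pregnancy,ej_total_count,51.79,1105.34,FALSE
discovery,pregnancy,ej_progressive_motility,18,74,FALSE
discovery,pregnancy,ej_immotile,2,62,FALSE
discovery,pregnancy,ej_total_motile,14.5,722.21,FALSE
discovery,pregnancy,ej_morphology,2,15,FALSE
discovery,pregnancy,ej_alkaline_comet,25,72,FALSE
discovery,pregnancy,ej_neutral_comet,33,90,FALSE
discovery,pregnancy,su_concentration,9.68,395.95,FALSE
discovery,pregnancy,su_total_count,3.87,158.38,FALSE
discovery,pregnancy,su_progressive_motility,38,93,FALSE
discovery,pregnancy,su_immotile,1,45,FALSE
discovery,pregnancy,su_total_motile,1.68,125.12,FALSE
discovery,pregnancy,su_alkaline_comet,22,59,FALSE
discovery,pregnancy,su_neutral_comet,26,82,FALSE
discovery,no_pregnancy,female_age,21,39,FALSE
discovery,no_pregnancy,bmi,18,45,FALSE
discovery,no_pregnancy,infertility_duration,5,120,FALSE
discovery,no_pregnancy,fsh,2.59,10.8,FALSE
discovery,no_pregnancy,lh,2.22,27.28,FALSE
discovery,no_pregnancy,estradiol,10,450,FALSE
discovery,no_pregnancy,prolactin,4.76,58,FALSE
discovery,no_pregnancy,antral_follicle_count,3,27,FALSE
discovery,pregnancy,female_age,24,38,FALSE
discovery,pregnancy,bmi,18,40,FALSE
discovery,pregnancy,infertility_duration,6,48,FALSE
discovery,pregnancy,fsh,4.47,11.4,FALSE
discovery,pregnancy,lh,2.58,17.81,FALSE
discovery,pregnancy,estradiol,21,87.4,FALSE
discovery,pregnancy,prolactin,4.76,42.57,FALSE
discovery,pregnancy,antral_follicle_count,6,30,FALSE
validation,pregnancy,male_age,25,41,FALSE
validation,pregnancy,semen_volume,1.6,7.3,FALSE
validation,pregnancy,ej_concentration,14.26,270.65,FALSE
validation,pregnancy,ej_total_count,68.5,984,FALSE
validation,pregnancy,ej_progressive_motility,6,79,FALSE
validation,pregnancy,ej_immotile,2,75,FALSE
validation,pregnancy,ej_total_motile,8.2,777,FALSE
validation,pregnancy,ej_morphology,0,6,FALSE
validation,pregnancy,ej_alkaline_comet,25,67,FALSE
validation,pregnancy,ej_neutral_comet,20,91,FALSE
validation,pregnancy,su_concentration,9.17,263.18,FALSE
validation,pregnancy,su_total_count,3.67,105.27,FALSE
validation,pregnancy,su_progressive_motility,36,94,FALSE
validation,pregnancy,su_immotile,1,40,FALSE
validation,pregnancy,su_total_motile,1.72,76,FALSE
validation,pregnancy,su_alkaline_comet,21,54,FALSE
validation,pregnancy,su_neutral_comet,22,65,FALSE
validation,no_pregnancy,male_age,26,44,TRUE
validation,no_pregnancy,semen_volume,0.5,8,TRUE
validation,no_pregnancy,ej_concentration,4,439,TRUE
validation,no_pregnancy,ej_total_count,12.5,1223,TRUE
validation,no_pregnancy,ej_progressive_motility,5,86,TRUE
validation,no_pregnancy,ej_immotile,1,86,TRUE
validation,no_pregnancy,ej_total_motile,2.5,819,TRUE
validation,no_pregnancy,ej_morphology,1,18,TRUE
validation,no_pregnancy,ej_alkaline_comet,22,82,TRUE
validation,no_pregnancy,ej_neutral_comet,23,91,TRUE
validation,no_pregnancy,su_concentration,1.19,395.95,TRUE
validation,no_pregnancy,su_total_count,0.48,158.38,TRUE
validation,no_pregnancy,su_progressive_motility,10,98,TRUE
validation,no_pregnancy,su_immotile,0,81,TRUE
validation,no_pregnancy,su_total_motile,0.26,125.12,TRUE
validation,no_pregnancy,su_alkaline_comet,20,75,TRUE
validation,no_pregnancy,su_neutral_comet,17,91,TRUE
validation,no_pregnancy,female_age,23,40,FALSE
validation,no_pregnancy,bmi,17.24,45,FALSE
validation,no_pregnancy,infertility_duration,6,84,FALSE
validation,no_pregnancy,fsh,1.58,10.49,FALSE
validation,no_pregnancy,lh,0.54,26.72,FALSE
validation,no_pregnancy,estradiol,6,384,FALSE
validation,no_pregnancy,prolactin,3.18,77.82,FALSE
validation,no_pregnancy,antral_follicle_count,4,26,FALSE
validation,pregnancy,female_age,26,39,FALSE
validation,pregnancy,bmi,17.24,35.7,FALSE
validation,pregnancy,infertility_duration,12,48,FALSE
validation,pregnancy,fsh,1.58,11.4,FALSE
validation,pregnancy,lh,0.54,18.63,FALSE
validation,pregnancy,estradiol,8,85,FALSE
validation,pregnancy,prolactin,4.32,77.82,FALSE
validation,pregnancy,antral_follicle_count,4,25,FALSE
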