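name,compartment,units,direction_policy,source_group,include_in_model
male_age,male_demographic,years,upper,pregnancy,TRUE
semen_volume,ejaculate,mL,none,pregnancy,FALSE
ej_concentration,ejaculate,10^6 sperm/mL,lower,pregnancy,TRUE
ej_total_count,ejaculate,10^6 sperm,lower,pregnancy,TRUE
ej_progressive_motility,ejaculate,%,lower,pregnancy,TRUE
ej_immotile,ejaculate,%,upper,pregnancy,TRUE
ej_total_motile,ejaculate,10^6 sperm,lower,pregnancy,TRUE
ej_morphology,ejaculate,% normal forms,lower,pregnancy,TRUE
ej_alkaline_comet,ejaculate,% affected sperm,upper,pregnancy,TRUE
ej_neutral_comet,ejaculate,% affected sperm,upper,pregnancy,TRUE
su_concentration,swim_up,10^6 sperm/mL,none,pregnancy,FALSE
su_total_count,swim_up,10^6 sperm,none,pregnancy,FALSE
su_progressive_motility,swim_up,%,lower,pregnancy,TRUE
su_immotile,swim_up,%,upper,pregnancy,TRUE
su_total_motile,swim_up,10^6 sperm,none,pregnancy,FALSE
su_alkaline_comet,swim_up,% affected sperm,upper,pregnancy,TRUE
su_neutral_comet,swim_up,% affected sperm,upper,pregnancy,TRUE
female_age,female,years,upper,no_pregnancy,TRUE
bmi,female,kg/m^2,upper,no_pregnancy,TRUE
infertility_duration,female,months,upper,no_pregnancy,TRUE
fsh,female,mUI/mL,none,no_pregnancy,FALSE
lh,female,mUI/mL,upper,no_pregnancy,TRUE
estradiol,female,pg/mL,lower,no_pregnancy,TRUE
prolactin,female,ng/mL,none,no_pregnancy,FALSE
antral_follicle_count,female,count,lower,no_pregnancy,TRUE
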