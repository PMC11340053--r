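variable,level,n,percentage
ethnicity,Gedeo,63,33.33
ethnicity,Oromo,63,33.33
ethnicity,Sidama,63,33.33
age,35-44,33,17
age,45-54,45,24
age,55-64,88,47
age,65+,23,12
gender,Male,133,70
gender,Female,56,30
education,Illiterate,89,47
education,Primary,81,43
education,Secondary,19,10
religion,Protestant,101,53
religion,Orthodox,13,7
religion,Islam,75,40
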