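variable,level,n,mean,sd,p_value
age,Young (35-44),33,4.73,0.94,0.0001
age,Middle age (45-54),45,6.84,1.74,0.0001
age,Older (55-64),88,7.9,1.72,0.0001
age,Elderly (65+),23,5.09,1.47,0.0001
gender,Male,133,6.76,2.02,0.77
gender,Female,56,6.73,2.09,0.77
education,Illiterate,89,6.74,2.03,0.54
education,Primary,81,6.86,2.09,0.54
education,Secondary,19,6.37,1.89,0.54
religion,Protestant,101,6.51,2.04,0.11
religion,Islam,75,7.04,1.95,0.11
religion,Orthodox,13,8.33,3.21,0.11
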