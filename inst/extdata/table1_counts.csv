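variable,level,downward,twoway
age,le_65,2504,3912
age,gt_65,211,141
gender,man,1348,2087
gender,woman,1367,1966
marriage,partnered,2594,3933
marriage,without_partner,121,120
education,less_lower_secondary,2320,3315
education,upper_secondary_vocational,337,650
education,tertiary,58,88
urban,rural,1122,1719
urban,urban,1593,2334
drinking,no,1748,2503
drinking,yes,967,1550
smoking,no,1616,2417
smoking,yes,1099,1636
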