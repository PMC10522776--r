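region,year,age_group,deaths_female_thousands,deaths_male_thousands,male_share_printed_pct
World,1990,0-4,6040,6790,52.9
World,1990,5-14,771,861,52.8
World,1990,15-24,727,975,57.3
World,2021,0-4,2300,2740,54.4
World,2021,5-14,370,459,55.4
World,2021,15-24,472,831,63.8
South Asia,1990,0-4,2400,2480,50.8
South Asia,1990,5-14,290,291,50.1
South Asia,1990,15-24,290,254,46.7
South Asia,2021,0-4,607,681,52.9
South Asia,2021,5-14,69,95,57.9
South Asia,2021,15-24,129,201,60.9
Latin America and the Caribbean,1990,0-4,291,359,55.2
Latin America and the Caribbean,1990,5-14,25,34,57.6
Latin America and the Caribbean,1990,15-24,38,89,70.1
Latin America and the Caribbean,2021,0-4,68,87,56.1
Latin America and the Caribbean,2021,5-14,12,16,57.1
Latin America and the Caribbean,2021,15-24,28,96,77.4
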