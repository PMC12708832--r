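dimension,level,n_studies,pct_studies,n_women,n_total,printed_pct_women
total,Total,1593,100,716569,1859736,38.5
year,2018,290,18.2,152184,427274,35.6
year,2019,265,16.6,125146,318213,39.3
year,2020,279,17.5,64067,187893,34.1
year,2021,218,13.7,109546,272434,40.2
year,2022,124,7.8,118822,263316,45.1
year,2023,136,8.5,44741,119508,37.4
year,2024,281,17.6,102063,271098,37.6
entity,IschemicHeartDisease,337,21.2,156862,559595,28.0
entity,OtherCVD,369,23.2,245371,551316,44.3
entity,Stroke,289,18.1,72629,189563,38.3
entity,SystemicHypertension,179,11.2,55812,123178,45.3
entity,HeartFailure,186,11.7,58257,155470,37.5
entity,AtrialFibrillation,119,7.5,104002,225393,46.1
entity,LowerExtremity,42,2.6,5546,16969,32.7
entity,ValveEndocarditis,47,3.0,16114,34950,46.1
entity,PulmonaryHypertension,25,1.6,1976,3302,59.8
region,Europe,591,37.1,176479,487242,36.2
region,Northern America,585,36.7,371953,923290,40.3
region,Latin America and Caribbean,57,3.6,9620,24464,39.3
region,Northern Africa and Western Asia,35,2.2,3199,8660,36.9
region,Sub-Saharan Africa,4,0.3,617,1151,53.6
region,Central and Southern Asia,15,0.9,9289,31448,29.5
region,Eastern and South-Eastern Asia,283,17.8,115715,324749,35.6
region,Oceania,23,1.4,29697,58732,50.6
size_quartile,First (<= 72),399,25.0,6819,16955,40.2
size_quartile,Second (72 < x <= 182),400,25.1,18665,47780,39.1
size_quartile,Third (182 < x <= 617),396,24.9,49896,128890,38.7
size_quartile,Fourth (> 617),398,25.0,641189,1666111,38.5
leading_author,Yes,789,49.5,336715,815604,41.3
leading_author,No,804,50.5,379854,1044132,36.4
sgr_subsample,All,632,39.7,310349,769761,36.3
sgr_subsample,Less than 3 of 4,384,60.8,79596,237907,33.4
sgr_subsample,At least 3 of 4,248,39.2,230753,531854,43.4
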