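country,y2021,y2025,y2030,nil
Angola,79,69,57,FALSE
Burkina Faso,39,31,24,FALSE
Benin,60,54,48,FALSE
Botswana,47,39,30,FALSE
Burundi,48,39,25,FALSE
Cameroon,50,39,25,FALSE
CAR,110,105,94,FALSE
Côte d'Ivoire,NA,NA,NA,TRUE
Eswatini,46,36,25,FALSE
Gambia,39,31,24,FALSE
Kenya,75,68,60,FALSE
Lesotho,84,73,55,FALSE
Mauritania,76,68,60,FALSE
Mozambique,68,60,53,FALSE
Namibia,42,35,22,FALSE
Niger,54,47,39,FALSE
Nigeria,85,74,60,FALSE
Rwanda,34,28,23,FALSE
Sierra Leone,NA,NA,NA,TRUE
South Africa,23,18,12,FALSE
Senegal,32,25,15,FALSE
Sudan,45,40,33,FALSE
Tanzania,39,32,25,FALSE
Togo,47,39,28,FALSE
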