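country,y2021,y2025,y2030,nil
Angola,72,57,42,FALSE
Burkina Faso,30,22,13,FALSE
Benin,53,43,35,FALSE
Botswana,40,30,21,FALSE
Burundi,41,30,18,FALSE
Cameroon,44,32,18,FALSE
CAR,105,90,75,FALSE
Côte d'Ivoire,NA,NA,NA,TRUE
Eswatini,41,29,18,FALSE
Gambia,33,25,17,FALSE
Kenya,68,57,46,FALSE
Lesotho,79,62,41,FALSE
Mauritania,69,56,46,FALSE
Mozambique,61,49,40,FALSE
Namibia,36,27,13,FALSE
Niger,47,37,27,FALSE
Nigeria,78,62,45,FALSE
Rwanda,28,20,14,FALSE
Sierra Leone,NA,NA,NA,TRUE
South Africa,21,16,10,FALSE
Senegal,30,21,9,FALSE
Sudan,43,39,25,FALSE
Tanzania,38,27,19,FALSE
Togo,44,38,23,FALSE
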