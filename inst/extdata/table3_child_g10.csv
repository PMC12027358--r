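country,y2021,y2025,y2030,nil
Angola,86,82,74,FALSE
Burkina Faso,42,40,34,FALSE
Benin,67,65,63,FALSE
Botswana,54,49,44,FALSE
Burundi,55,49,40,FALSE
Cameroon,58,52,40,FALSE
CAR,121,121,120,FALSE
Côte d'Ivoire,NA,NA,NA,TRUE
Eswatini,55,48,39,FALSE
Gambia,45,43,41,FALSE
Kenya,82,81,80,FALSE
Lesotho,93,87,72,FALSE
Mauritania,83,80,78,FALSE
Mozambique,75,72,70,FALSE
Namibia,49,45,34,FALSE
Niger,61,57,52,FALSE
Nigeria,92,87,77,FALSE
Rwanda,40,37,35,FALSE
Sierra Leone,NA,NA,NA,TRUE
South Africa,29,26,21,FALSE
Senegal,38,33,18,FALSE
Sudan,52,50,47,FALSE
Tanzania,45,41,36,FALSE
Togo,54,49,40,FALSE
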