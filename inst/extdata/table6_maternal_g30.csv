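country,y2021,y2025,y2030,nil
Angola,209,150,94,FALSE
Burkina Faso,270,209,152,FALSE
Benin,338,267,198,FALSE
Botswana,120,89,59,FALSE
Burundi,496,389,276,FALSE
Cameroon,485,390,301,FALSE
CAR,748,615,490,FALSE
Côte d'Ivoire,560,456,352,FALSE
Eswatini,392,335,263,FALSE
Gambia,220,175,133,FALSE
Kenya,313,226,142,FALSE
Lesotho,510,387,268,FALSE
Mauritania,692,550,420,FALSE
Mozambique,231,150,89,FALSE
Namibia,160,117,70,FALSE
Niger,445,317,201,FALSE
Nigeria,851,685,512,FALSE
Rwanda,207,184,133,FALSE
Sierra Leone,NA,NA,NA,TRUE
South Africa,96,71,46,FALSE
Senegal,262,187,116,FALSE
Sudan,252,186,120,FALSE
Tanzania,466,359,259,FALSE
Togo,360,296,231,FALSE
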