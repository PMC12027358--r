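country,y2021,y2025,y2030,nil
Angola,229,193,145,FALSE
Burkina Faso,293,263,225,FALSE
Benin,364,332,289,FALSE
Botswana,136,120,103,FALSE
Burundi,528,478,397,FALSE
Cameroon,517,485,431,FALSE
CAR,792,748,694,FALSE
Côte d'Ivoire,596,558,502,FALSE
Eswatini,426,414,380,FALSE
Gambia,240,222,199,FALSE
Kenya,337,284,211,FALSE
Lesotho,556,521,456,FALSE
Mauritania,755,734,703,FALSE
Mozambique,253,193,138,FALSE
Namibia,178,152,114,FALSE
Niger,475,392,294,FALSE
Nigeria,899,833,724,FALSE
Rwanda,227,209,199,FALSE
Sierra Leone,NA,NA,NA,TRUE
South Africa,112,98,79,FALSE
Senegal,284,237,176,FALSE
Sudan,274,236,181,FALSE
Tanzania,498,442,373,FALSE
Togo,386,367,335,FALSE
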