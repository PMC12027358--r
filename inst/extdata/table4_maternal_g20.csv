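country,y2021,y2025,y2030,nil
Angola,219,171,118,FALSE
Burkina Faso,281,235,186,FALSE
Benin,351,298,240,FALSE
Botswana,128,104,82,FALSE
Burundi,512,435,332,FALSE
Cameroon,501,438,361,FALSE
CAR,770,679,584,FALSE
Côte d'Ivoire,578,505,421,FALSE
Eswatini,412,373,317,FALSE
Gambia,230,198,164,FALSE
Kenya,325,254,174,FALSE
Lesotho,527,430,323,FALSE
Mauritania,734,666,592,FALSE
Mozambique,242,171,112,FALSE
Namibia,169,134,91,FALSE
Niger,460,353,244,FALSE
Nigeria,875,756,610,FALSE
Rwanda,217,186,164,FALSE
Sierra Leone,NA,NA,NA,TRUE
South Africa,104,84,62,FALSE
Senegal,275,211,144,FALSE
Sudan,263,210,148,FALSE
Tanzania,482,399,312,FALSE
Togo,373,330,279,FALSE
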