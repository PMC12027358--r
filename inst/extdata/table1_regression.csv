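country,maternal_constant,maternal_constant_se,maternal_constant_stars,maternal_beta,maternal_beta_se,maternal_beta_stars,child_constant,child_constant_se,child_constant_stars,child_beta,child_beta_se,child_beta_stars
Angola,0.3833,0.1802,**,-0.0487,0.0253,*,0.3417,0.2855,,-0.0241,0.0267,
Burkina Faso,0.2350,0.1289,*,-0.0211,0.0173,,-0.4235,0.1971,**,-0.0345,0.0318,
Benin,-0.1024,0.2296,,-0.0073,0.0086,,0.6212,0.2238,**,-0.00003,0.0042,
Botswana,0.1998,0.3042,,-0.0134,0.0147,,0.3634,0.1765,*,-0.0176,0.0098,*
Burundi,0.3571,0.1396,**,-0.0444,0.0223,**,0.2629,0.0584,***,-0.0611,0.0132,***
Cameroon,-0.0474,0.1526,,-0.0169,0.0122,,-0.3046,0.0776,***,-0.0288,0.0077,***
CAR,0.8856,0.6401,,-0.0057,0.0182,,0.7619,0.3513,**,-0.0013,0.0005,**
Côte d'Ivoire,0.0470,0.2947,,-0.0107,0.0049,**,0.0828,0.0332,***,0.0162,0.0032,***
Eswatini,1.3503,0.2642,***,-0.0444,0.0084,***,3.1321,0.8269,***,-0.0625,0.0149,***
Gambia,0.2151,0.1953,,-0.0107,0.0076,,0.4274,0.1272,***,-0.0146,0.0054,**
Kenya,0.9180,0.3985,**,-0.0905,0.0666,,0.2957,0.0680,***,-0.0055,0.0010,***
Lesotho,1.7660,0.6734,**,-0.0818,0.0288,***,0.7056,0.4219,,-0.0111,0.0155,
Mauritania,0.3311,0.2511,,-0.0074,0.0029,**,0.2069,0.0673,***,-0.0094,0.0019,***
Mozambique,5.0635,1.0313,,-0.0006,0.0061,,0.3215,0.0708,***,-0.0003,0.0076,
Namibia,0.5101,0.4279,,-0.0596,0.0371,,0.3195,0.3019,,-0.0966,0.0475,*
Niger,2.1183,0.6618,***,-0.0117,0.0062,*,0.2292,0.0541,***,-0.0133,0.0136,
Nigeria,0.5917,0.0948,***,-0.0380,0.0074,***,0.1329,0.0665,*,-0.0328,0.0066,***
Rwanda,1.2979,0.4721,**,-0.0357,0.0449,,1.0869,0.3450,***,-0.0075,0.0286,
Sierra Leone,0.3608,0.1152,***,0.0343,0.0074,***,0.0601,0.0599,,0.0098,0.0032,***
South Africa,0.4511,0.3919,,-0.0364,0.0204,*,1.1223,0.3392,***,-0.0838,0.0233,***
Senegal,-0.0670,0.1615,,-0.0216,0.0378,,-0.2318,0.0465,***,-0.1414,0.0173,***
Sudan,0.4719,0.2007,**,-0.0559,0.0184,***,0.2571,0.0285,***,-0.0159,0.0035,***
Tanzania,2.3167,0.6448,**,-0.0068,0.0076,,0.2109,0.0498,***,-0.0270,0.0118,**
Togo,0.0974,0.1718,,-0.0137,0.0067,*,0.7327,0.2506,***,-0.0061,0.0033,*
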