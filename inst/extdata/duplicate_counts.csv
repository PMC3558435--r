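site,class,count_1,count_2,diff_abs,diff_pct,known_discrepancy
Kutupalong,residential,371,371,0,0.0,FALSE
Kutupalong,other,440,444,4,0.9,FALSE
Kutupalong,total,811,815,4,0.5,FALSE
Breidjing,residential,5423,6208,785,12.6,FALSE
Breidjing,other,564,903,339,37.5,FALSE
Breidjing,total,5987,7111,1124,18.8,TRUE
Farchana,residential,4181,3466,715,17.1,FALSE
Farchana,other,493,900,407,45.2,FALSE
Farchana,total,4674,4366,308,6.6,FALSE
Bambu,residential,1501,1380,121,8.1,FALSE
Bambu,other,41,50,9,18.0,FALSE
Bambu,total,1542,1430,112,7.3,FALSE
Mugunga III,residential,588,518,70,11.9,FALSE
Mugunga III,other,2,129,127,98.4,FALSE
Mugunga III,total,590,647,57,8.8,FALSE
Sherkole,residential,2643,2746,103,3.8,FALSE
Sherkole,other,251,217,34,13.5,FALSE
Sherkole,total,2894,2963,69,2.3,FALSE
Shimelba,residential,2500,2604,104,4.0,FALSE
Shimelba,other,741,408,333,44.9,FALSE
Shimelba,total,3241,3012,229,7.1,FALSE
Champs-de-Mars,residential,2169,2552,383,15.0,FALSE
Champs-de-Mars,other,70,0,70,100.0,FALSE
Champs-de-Mars,total,2239,2552,313,12.3,FALSE
"Delmas 24, Sollino, Fort National",residential,2929,4849,1920,39.6,FALSE
"Delmas 24, Sollino, Fort National",other,430,472,42,8.9,FALSE
"Delmas 24, Sollino, Fort National",total,3359,5321,1962,36.9,FALSE
Kakuma,residential,16690,11342,1137,9.1,TRUE
Kakuma,other,2661,2305,904,39.2,TRUE
Kakuma,total,19351,13647,233,1.7,TRUE
Bairro Esturro,residential,1643,1194,449,27.3,FALSE
Bairro Esturro,other,242,222,20,8.3,FALSE
Bairro Esturro,total,1885,1416,469,24.9,FALSE
Kutupalong makeshift,residential,3708,NA,NA,NA,FALSE
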