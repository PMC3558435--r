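site,country,settlement_type,reference_population,reference_method,reference_date,image_date
Kutupalong,Bangladesh,refugee_camp,11047,UNHCR registration,2009-12-31,2010-01-29
Breidjing,Chad,refugee_camp,26770,UNHCR registration,2005-12-31,2006-01-30
Farchana,Chad,refugee_camp,19070,UNHCR registration,2004-12-31,2004-10-11
Bambu,Democratic Republic of Congo,IDP_camp,5871,UNOPS demographic surveillance,2010-01-31,2010-01-29
Mugunga III,Democratic Republic of Congo,IDP_camp,1969,UNOPS demographic surveillance,2010-01-31,2010-01-29
Sherkole,Ethiopia,refugee_camp,13958,UNHCR registration,2006-12-31,2006-11-08
Shimelba,Ethiopia,refugee_camp,13043,UNHCR registration,2006-12-31,2006-10-29
Champs-de-Mars,Haiti,informal_IDP_camp,23214,MSF/Epicentre census,2010-04-22,2010-04-30
"Delmas 24, Sollino, Fort National",Haiti,urban_mixed,39349,MSF/Epicentre census,2010-05-13,2010-05-11
Kakuma,Kenya,refugee_camp,90457,UNHCR registration,2006-12-31,2007-01-14
Bairro Esturro,Mozambique,urban_mixed,9523,T-square method,2004-08-15,2004-08-15
Kutupalong makeshift,Bangladesh,makeshift_camp,NA,none,NA,2010-01-29
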