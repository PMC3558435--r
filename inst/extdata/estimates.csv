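site,mean_count,occupancy_per_unit,households_multiplier,structure_occupancy,population,reference_population,diff_abs,diff_pct,info_index,n_reports,count_override
Kutupalong,371,6.5,5,32.5,12058,11047,1011,9.2,789,6,FALSE
Breidjing,5816,6.0,1,6.0,34896,26770,8126,30.4,800,3,FALSE
Farchana,3824,6.0,1,6.0,22944,19070,3874,20.3,808,3,FALSE
Bambu,1441,5.3,1,5.3,7637,5871,1766,30.1,452,11,FALSE
Mugunga III,553,5.4,1,5.4,2986,1969,1017,51.7,436,11,FALSE
Sherkole,2695,3.1,1,3.1,8355,13958,-5603,-40.1,16,1,FALSE
Shimelba,2552,4.7,1,4.7,11994,13043,-1049,-8.0,60,1,FALSE
Champs-de-Mars,2361,5.3,1,5.3,12513,23214,-10701,-46.1,880,5,FALSE
"Delmas 24, Sollino, Fort National",3889,5.3,1,5.3,20612,39349,-18737,-47.6,880,5,FALSE
Kakuma,16690,5.3,1,5.3,88457,90457,-2000,-2.2,428,4,TRUE
Bairro Esturro,1419,6.3,1,6.3,8940,9523,-583,-6.1,252,7,FALSE
Kutupalong makeshift,3708,6.5,1,6.5,24102,NA,NA,NA,NA,NA,FALSE
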