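population,site_name,country,latitude,longitude,altitude_m,n_males,order_index
ARU,Arudy,France,43.10028,-0.44389,400,41,1
GAB,Gabas,France,42.90000,-0.43333,1020,7,2
HER,L'Hermine,France,42.86300,-0.39178,1209,7,3
POR,Portalet,France,42.80083,-0.41500,1708,12,4
CM,Corral de Mulas,Spain,42.78594,-0.39289,1569,8,5
PAZ,Camino Pazino,Spain,42.76597,-0.34275,1343,10,6
ESC,Escarrilla,Spain,42.73169,-0.31092,1130,42,7
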