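species,genus,stage,water_status,mean_pct,se_pct,snk_letter,significant_decline
Populus euphratica (S1),Populus,green,fresh,85,5.77,a,FALSE
Populus euphratica (S1),Populus,yellow,fresh,100,0,a,FALSE
Populus euphratica (S1),Populus,start_dehiscence,fresh,98.33,1.67,a,FALSE
Populus euphratica (S1),Populus,fully_dehiscing,fresh,81.67,8.33,a,FALSE
Populus euphratica (S1),Populus,dispersed,fresh,1.67,1.67,b,FALSE
Populus euphratica (S1),Populus,green,dry,42.5,4.33,c,TRUE
Populus euphratica (S1),Populus,yellow,dry,100,0,a,FALSE
Populus euphratica (S1),Populus,start_dehiscence,dry,96.67,1.67,a,FALSE
Populus euphratica (S1),Populus,fully_dehiscing,dry,78.33,2.89,b,FALSE
Populus euphratica (S1),Populus,dispersed,dry,0,0,d,FALSE
Populus davidiana,Populus,green,fresh,86,8.57,a,FALSE
Populus davidiana,Populus,yellow,fresh,100,0,a,FALSE
Populus davidiana,Populus,start_dehiscence,fresh,99,1,a,FALSE
Populus davidiana,Populus,fully_dehiscing,fresh,90,2.24,a,FALSE
Populus davidiana,Populus,dispersed,fresh,77,7,a,FALSE
Populus davidiana,Populus,green,dry,67,4.64,c,FALSE
Populus davidiana,Populus,yellow,dry,100,0,a,FALSE
Populus davidiana,Populus,start_dehiscence,dry,100,0,a,FALSE
Populus davidiana,Populus,fully_dehiscing,dry,86,1.87,b,FALSE
Populus davidiana,Populus,dispersed,dry,71,3.67,c,FALSE
Salix babylonica (S1),Salix,green,fresh,80,5.70,a,FALSE
Salix babylonica (S1),Salix,yellow,fresh,100,0,a,FALSE
Salix babylonica (S1),Salix,start_dehiscence,fresh,98.67,1.33,a,FALSE
Salix babylonica (S1),Salix,fully_dehiscing,fresh,60,7.64,b,FALSE
Salix babylonica (S1),Salix,dispersed,fresh,26.67,5.70,c,FALSE
Salix babylonica (S1),Salix,green,dry,86,4.58,b,FALSE
Salix babylonica (S1),Salix,yellow,dry,100,0,a,FALSE
Salix babylonica (S1),Salix,start_dehiscence,dry,95.33,0.67,"a, b",FALSE
Salix babylonica (S1),Salix,fully_dehiscing,dry,60,2.89,c,FALSE
Salix babylonica (S1),Salix,dispersed,dry,18,1.15,d,FALSE
Salix psilostigma,Salix,green,fresh,98.33,1.67,a,FALSE
Salix psilostigma,Salix,yellow,fresh,100,0,a,FALSE
Salix psilostigma,Salix,start_dehiscence,fresh,100,0,a,FALSE
Salix psilostigma,Salix,fully_dehiscing,fresh,96.67,1.67,a,FALSE
Salix psilostigma,Salix,dispersed,fresh,NA,NA,NA,FALSE
Salix psilostigma,Salix,green,dry,7,2.54,c,TRUE
Salix psilostigma,Salix,yellow,dry,100,0,a,FALSE
Salix psilostigma,Salix,start_dehiscence,dry,100,0,a,FALSE
Salix psilostigma,Salix,fully_dehiscing,dry,90,2.74,b,FALSE
Salix psilostigma,Salix,dispersed,dry,NA,NA,NA,FALSE
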