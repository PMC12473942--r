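lot_id,species,genus,collection_date,latitude,longitude,elevation_m,tsw_mg
P_alba_S1,Populus alba,Populus,2020-04-23,38.4167,106.1667,1077,379.6
P_alba_S2,Populus alba,Populus,2020-04-13,37.7333,107.3167,1378,312.0
P_euphratica_S1,Populus euphratica,Populus,2019-09-20,41.1500,86.1000,820,NA
P_euphratica_S2,Populus euphratica,Populus,2020-09-18,40.5333,81.2833,960,61.2
P_hopeiensis,Populus x hopeiensis,Populus,2020-04-13,37.7333,107.3167,1377,197.2
P_simonii,Populus simonii,Populus,2020-04-15,37.7333,107.0667,1467,509.6
P_davidiana,Populus davidiana,Populus,2020-03-29,25.2333,102.7333,1915,110.0
P_rotundifolia,Populus rotundifolia,Populus,2020-05-15,25.1333,102.7333,1882,136.4
P_tomentosa,Populus tomentosa,Populus,2020-04-22,38.4667,106.2000,1105,311.2
P_cathayana,Populus cathayana,Populus,2020-07-13,41.3667,111.7333,619,581.2
S_babylonica_S1,Salix babylonica,Salix,2020-03-29,25.0167,102.6667,1856,131.2
S_babylonica_S2,Salix babylonica,Salix,2020-04-19,40.0000,116.3167,35,132.0
S_cavaleriei,Salix cavaleriei,Salix,2020-09-25,25.0667,102.3667,1768,219.6
S_matsudana,Salix matsudana,Salix,2020-04,38.5000,106.2500,1104,100.8
S_radinostachya,Salix radinostachya,Salix,2020-05-25,25.1333,102.7333,1931,68.8
S_cheilophila,Salix cheilophila,Salix,2020-04-15,37.7333,107.0667,1468,76.4
S_psammophila,Salix psammophila,Salix,2020-04-13,37.7333,107.3167,1396,76.4
S_wilhelmsiana,Salix wilhelmsiana,Salix,2020-05-11,38.4167,106.1667,1115,62.0
S_psilostigma,Salix psilostigma,Salix,2020-05-23,25.2167,99.2833,2299,96.8
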