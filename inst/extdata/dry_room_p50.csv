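lot_id,species,genus,p50_d
S_cavaleriei,Salix cavaleriei,Salix,263
S_matsudana,Salix matsudana,Salix,144
S_radinostachya,Salix radinostachya,Salix,192
S_babylonica_S1,Salix babylonica,Salix,205
S_babylonica_S2,Salix babylonica,Salix,312
S_cheilophila,Salix cheilophila,Salix,309
S_psammophila,Salix psammophila,Salix,341
S_psilostigma,Salix psilostigma,Salix,306
P_euphratica_S2,Populus euphratica,Populus,597
P_alba_S1,Populus alba,Populus,297
P_alba_S2,Populus alba,Populus,271
P_hopeiensis,Populus x hopeiensis,Populus,209
P_simonii,Populus simonii,Populus,497
P_rotundifolia,Populus rotundifolia,Populus,1047
P_davidiana,Populus davidiana,Populus,1481
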