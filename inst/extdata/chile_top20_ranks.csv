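metric,species,rank
RED,Lactoris fernandeziana,1
RED,Juania australis,2
RED,Tecophilaea cyanocrocus,3
RED,Placea amoena,4
RED,Leontochir ovallei,5
RED,Placea lutea,6
RED,Megalachne masafuerana,7
RED,Megalachne berteroana,8
RED,Cuminia eriantha,9
RED,Metharme lanata,10
RED,Sanctambrosia manicata,11
RED,Gomortega keule,12
RED,Nothomyrcia fernandeziana,13
RED,Nesocaryum stylosum,14
RED,Leucocoryne foetida,15
RED,Rimacactus laui,16
RED,Valdivia gayana,17
RED,Ochagavia elegans,18
RED,Pintoa chilensis,19
RED,Yunquea tenzii,20
iucn50,Lactoris fernandeziana,1
iucn50,Gomortega keule,2
iucn50,Leontochir ovallei,3
iucn50,Juania australis,4
iucn50,Placea amoena,5
iucn50,Tecophilaea cyanocrocus,6
iucn50,Megalachne masafuerana,7
iucn50,Metharme lanata,8
iucn50,Pintoa chilensis,8
iucn50,Pitavia punctata,9
iucn50,Cuminia eriantha,10
iucn50,Sanctambrosia manicata,11
iucn50,Placea lutea,12
iucn50,Conanthera urceolata,13
iucn50,Legrandia concinna,14
iucn50,Avellanita bustillosii,15
iucn50,Gethyum atropurpureum,16
iucn50,Nesocaryum stylosum,17
iucn50,Miersia cornuta,18
iucn50,Microphyes robusta,19
iucn50,Selkirkia berteroi,20
iucn100,Lactoris fernandeziana,1
iucn100,Gomortega keule,2
iucn100,Leontochir ovallei,3
iucn100,Megalachne masafuerana,4
iucn100,Juania australis,5
iucn100,Placea amoena,6
iucn100,Cuminia eriantha,7
iucn100,Tecophilaea cyanocrocus,8
iucn100,Sanctambrosia manicata,9
iucn100,Metharme lanata,10
iucn100,Pintoa chilensis,10
iucn100,Pitavia punctata,11
iucn100,Nesocaryum stylosum,12
iucn100,Placea lutea,13
iucn100,Conanthera urceolata,14
iucn100,Legrandia concinna,15
iucn100,Avellanita bustillosii,16
iucn100,Gethyum atropurpureum,17
iucn100,Miersia cornuta,18
iucn100,Microphyes robusta,19
iucn100,Neoporteria sociabilis,20
iucn500,Lactoris fernandeziana,1
iucn500,Gomortega keule,2
iucn500,Leontochir ovallei,3
iucn500,Juania australis,4
iucn500,Placea amoena,5
iucn500,Tecophilaea cyanocrocus,6
iucn500,Metharme lanata,7
iucn500,Pintoa chilensis,7
iucn500,Pitavia punctata,8
iucn500,Megalachne masafuerana,9
iucn500,Placea lutea,10
iucn500,Conanthera urceolata,11
iucn500,Jubaea chilensis,12
iucn500,Legrandia concinna,13
iucn500,Avellanita bustillosii,14
iucn500,Cuminia eriantha,15
iucn500,Gethyum atropurpureum,16
iucn500,Sanctambrosia manicata,17
iucn500,Miersia cornuta,18
iucn500,Nesocaryum stylosum,19
iucn500,Microphyes robusta,20
isaac,Lactoris fernandeziana,1
isaac,Gomortega keule,2
isaac,Leontochir ovallei,3
isaac,Juania australis,4
isaac,Megalachne masafuerana,5
isaac,Placea amoena,6
isaac,Tecophilaea cyanocrocus,7
isaac,Cuminia eriantha,8
isaac,Metharme lanata,9
isaac,Pintoa chilensis,9
isaac,Sanctambrosia manicata,10
isaac,Pitavia punctata,11
isaac,Jubaea chilensis,12
isaac,Placea lutea,13
isaac,Nesocaryum stylosum,14
isaac,Conanthera urceolata,15
isaac,Legrandia concinna,16
isaac,Avellanita bustillosii,17
isaac,Gethyum atropurpureum,18
isaac,Miersia cornuta,19
isaac,Megalachne berteroana,20
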