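axis,class,horizon,lower,upper
continentality,hyperoceanic,ultrahyperoceanic,0,4
continentality,hyperoceanic,euhyperoceanic,4,8
continentality,hyperoceanic,subhyperoceanic,8,11
continentality,oceanic,semihyperoceanic,11,14
continentality,oceanic,euoceanic,14,17
continentality,oceanic,semicontinental,17,21
continentality,continental,subcontinental,21,28
continentality,continental,eucontinental,28,46
continentality,continental,hypercontinental,46,66
ombrotype,ultrahyperarid,lower ultrahyperarid,0,0.1
ombrotype,ultrahyperarid,upper ultrahyperarid,0.1,0.2
ombrotype,hyperarid,lower hyperarid,0.2,0.3
ombrotype,hyperarid,upper hyperarid,0.3,0.4
ombrotype,arid,lower arid,0.4,0.7
ombrotype,arid,upper arid,0.7,1.0
ombrotype,semiarid,lower semiarid,1.0,1.5
ombrotype,semiarid,upper semiarid,1.5,2.0
ombrotype,dry,lower dry,2.0,2.8
ombrotype,dry,upper dry,2.8,3.6
ombrotype,subhumid,lower subhumid,3.6,4.8
ombrotype,subhumid,upper subhumid,4.8,6.0
ombrotype,humid,lower humid,6.0,9.0
ombrotype,humid,upper humid,9.0,12.0
ombrotype,hyperhumid,lower hyperhumid,12.0,18.0
ombrotype,hyperhumid,upper hyperhumid,18.0,24.0
ombrotype,ultrahyperhumid,ultrahyperhumid,24.0,Inf
thermotype_med_itc,supramediterranean,upper supramediterranean,150,185
thermotype_med_itc,supramediterranean,lower supramediterranean,185,220
thermotype_med_itc,mesomediterranean,upper mesomediterranean,220,285
thermotype_med_itc,mesomediterranean,lower mesomediterranean,285,350
thermotype_med_itc,thermomediterranean,upper thermomediterranean,350,400
thermotype_med_itc,thermomediterranean,lower thermomediterranean,400,450
thermotype_med_itc,inframediterranean,upper inframediterranean,450,515
thermotype_med_itc,inframediterranean,lower inframediterranean,515,580
thermotype_med_tp,cryoromediterranean,upper cryoromediterranean,1,225
thermotype_med_tp,cryoromediterranean,lower cryoromediterranean,225,450
thermotype_med_tp,oromediterranean,upper oromediterranean,450,675
thermotype_med_tp,oromediterranean,lower oromediterranean,675,900
thermotype_med_tp,supramediterranean,upper supramediterranean,900,1200
thermotype_med_tp,supramediterranean,lower supramediterranean,1200,1500
thermotype_tem_itc,supratemperate,upper supratemperate,100,140
thermotype_tem_itc,supratemperate,lower supratemperate,140,180
thermotype_tem_itc,mesotemperate,upper mesotemperate,180,235
thermotype_tem_itc,mesotemperate,lower mesotemperate,235,290
thermotype_tem_itc,thermotemperate,upper thermotemperate,290,350
thermotype_tem_itc,thermotemperate,lower thermotemperate,350,410
thermotype_tem_itc,infratemperate,upper infratemperate,410,445
thermotype_tem_itc,infratemperate,lower infratemperate,445,480
thermotype_tem_tp,cryorotemperate,upper cryorotemperate,1,190
thermotype_tem_tp,cryorotemperate,lower cryorotemperate,190,380
thermotype_tem_tp,orotemperate,upper orotemperate,380,590
thermotype_tem_tp,orotemperate,lower orotemperate,590,800
thermotype_tem_tp,supratemperate,upper supratemperate,800,1100
thermotype_tem_tp,supratemperate,lower supratemperate,1100,1400
bioclimate_med,hyperdesertic,hyperdesertic,0,0.2
bioclimate_med,desertic,desertic,0.2,1.0
bioclimate_med,xeric,xeric,1.0,2.0
bioclimate_med,pluviseasonal,pluviseasonal,2.0,Inf
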