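"case_id","sex","age","bm_blasts","wbc","hb","platelets","npm1","flt3_tkd","mll_ptd","runx1","asxl1","tet2","idh1_r132","idh2_r140","idh2_r172","dnmt3a","flt3_itd_ratio","expression_pct","os_months","os_event","efs_months","efs_event"
"case_0001","female",60.3149212690736,65.1063210775408,67.6199495447028,7.74296814417153,54.7161716477548,"mut","wt","wt","mut","wt",,"wt","wt",,,0,52.7738900764892,15.4416457470506,FALSE,6.82039322769685,TRUE
"case_0002","female",71.0549188679322,88.4831602264169,177.791564203319,8.83396555678175,150.124520321835,"wt","wt","mut","wt","wt",,"wt","wt","wt",,0.275742769159842,135.530858432687,63.708514231024,TRUE,0.416495344765093,TRUE
"case_0003","female",57.9285028938549,85.6504711433712,142.608046473209,8.48039141895856,272.02145722065,"mut","wt","mut","wt","wt",,"wt",,"wt",,0,106.00211772736,33.4350819513202,FALSE,9.70783379214219,TRUE
"case_0004","female",58.1818066626232,71.3549592999039,50.1814334895591,8.93857464591901,135.809792087894,"mut","wt","wt","wt","wt",,,,"wt",,0,58.9144749260997,,,,
"case_0005","male",63.1279454868938,64.5968730437784,66.1310805901877,10.4569953667086,120.266274033474,"mut","wt","wt","wt","wt","wt","wt","wt","wt","wt",0,194.407340846569,,,,
"case_0006","female",72.837564739872,59.7259163674701,13.6032798413273,10.7719594812886,58.5517720987024,"mut","wt","mut","wt","wt",,,,"wt",,0,80.7349376163028,36.5643950822945,TRUE,6.1306800175844,TRUE
"case_0007","male",55.297819627585,74.5810430845463,101.727970971298,7.72329044195405,151.576555056645,"mut",,"wt","wt","wt",,,,"wt",,0,107.507264545144,30.8703260800902,FALSE,30.8703260800902,FALSE
"case_0008","male",88.2616864638709,92.4427961771559,101.094605723111,10.8675171268377,180.073734853341,"mut","wt","mut","wt","wt",,,"wt","wt","mut",0,122.832456561193,38.0617510126558,FALSE,0.363906996633749,TRUE
"case_0009","female",72.2647309349172,48.5734241492307,80.4813671004852,6.84419099632357,295.98917026566,"wt","wt","wt","mut","wt",,"wt",,"wt",,0,120.200689624439,13.0388502017925,TRUE,11.3061287260654,TRUE
"case_0010","male",32.4504367341988,46.9680222214077,13.2013450501751,8.4980652939758,96.5593112928022,"wt",,"wt","wt",,,"wt",,"wt",,0,138.766371303981,24.1782204592093,TRUE,24.1782204592093,TRUE
"case_0011","female",73.7344301537383,24.5814255317045,72.5958819554343,10.8279711563519,171.913033814728,"wt",,"wt","wt",,"wt","wt","wt",,,0,108.680035545623,38.2821758286811,FALSE,9.04147025850938,TRUE
"case_0012","female",64.6423122649654,54.139757635074,28.0316351729386,9.19984130266997,60.8879012391237,"wt","wt","mut","wt",,"wt","wt","mut","wt",,0,68.4217472595732,36.4577645435929,FALSE,18.5407599734203,TRUE
"case_0013","male",87.6693868665829,43.7518348489086,21.13060428995,11.7217054177202,33.9775277146496,"mut","mut","mut","wt","mut",,"wt","wt",,,0,68.3709710396696,12.7561941941526,TRUE,8.30713055955582,TRUE
"case_0014","male",49.4643427708831,99,72.0815918417177,10.4688342538066,73.9556479960568,"mut","wt","wt","mut","wt",,"mut",,"wt",,0,79.4476846507735,84,FALSE,45.3248523011287,TRUE
"case_0015","male",51.4336507131075,59.7421931820031,40.2167719961115,8.38292086021447,168.330475892771,"wt","wt","wt","wt","wt",,"wt","wt",,"mut",0,57.7757178466678,84,FALSE,59.8562034209875,TRUE
"case_0016","female",73.3409554467419,64.3587387116532,24.9614375799363,10.4090830977377,97.7678419655066,"wt","wt","wt","wt","wt",,"wt",,"wt",,0,351.307504298821,,,,
"case_0017","female",52.0270211610994,70.5885706013768,41.4477526003718,9.60123203804103,112.727034367509,"mut","mut","wt",,,"wt","wt","wt","wt",,0,185.616810567059,15.3799944904578,TRUE,15.3799944904578,TRUE
"case_0018","female",62.1144111569891,59.5883859529053,6.89996519499335,10.2061800432125,50.4366977053034,"mut","wt","wt","wt",,,,"wt",,,0,127.515806853833,84,FALSE,40.3136165872419,TRUE
"case_0019","male",57.9896463337965,51.2167672493894,56.2872732243922,14.3494533815507,93.3892486192403,"wt","wt","mut","wt","wt",,"wt",,"wt",,0,66.6745192109652,,,,
"case_0020","female",80.7539331577443,34.4542380421713,31.0211827720506,6.94633642810503,66.3573116778356,"wt","wt","wt","wt","mut",,"wt","wt",,,0,25.0550253359794,16.3212169557959,TRUE,16.3212169557959,TRUE
"case_0021","male",66.0653916135812,46.8515672850501,362.832436829793,10.07798391726,212.329423606478,"wt","mut","wt","wt","wt",,"wt","wt","wt",,0,168.648246427787,20.0750780786572,TRUE,4.42902015388954,TRUE
"case_0022","male",54.3392220999981,48.3727071513393,115.720103711049,7.43814664761257,76.835354927605,"wt","wt","wt","wt","wt","wt",,"wt","wt",,0.892818428480532,51.41795082039,54.9387154286437,TRUE,15.9387760737155,TRUE
"case_0023","female",44.5998660623686,58.0563806191738,55.6637651912335,6.37932342801914,145.609034631189,"mut","wt","wt",,"wt","wt","wt","wt","wt","mut",0.331872120150365,42.4931527399565,51.7310703342875,FALSE,51.7310703342875,FALSE
"case_0024","male",58.5257241957527,77.6869589609501,358.387925272611,10.0040797367589,158.437861278844,"wt","wt","wt","mut","mut","wt","wt",,"wt","wt",0,85.8903707588057,,,,
"case_0025","female",64.3778635597192,34.2860350983776,8.29684760113739,5.79102601915082,226.99115121063,"wt","wt","wt","mut","wt",,"wt","wt",,,0,84.6975585028819,,,,
"case_0026","female",67.3675960203676,35.0240209432013,68.5052207111812,7.82938934676565,45.7540091555771,"wt","wt","wt","mut","mut",,,,,,1.23975171142258,360.002649704399,2.77197962841436,TRUE,2.77197962841436,TRUE
"case_0027","male",67.4401603242148,93.486904108632,41.4350670607281,8.95795539849642,104.688534697825,"wt","wt","wt","wt","wt",,"wt","wt","wt","mut",0.870955096932594,73.9412153917087,31.8942133040983,FALSE,11.9816424901625,TRUE
"case_0028","female",74.4284109305367,73.1721228270965,29.2755327855592,8.17907731269869,40.9922826032688,"wt","wt","wt","mut","wt","wt","wt",,"wt",,0,293.312897441703,22.3906647016776,TRUE,1.96448312993725,TRUE
"case_0029","male",72.2572510432317,99,10.2870360171575,9.59459538776213,94.5449454941829,,"wt","wt","wt","wt",,"wt",,,,0.946938048955053,308.190703126801,84,FALSE,13.5698808583262,TRUE
"case_0030","male",68.7751958096934,91.5756330549567,400,8.03991302452009,181.466009545211,"mut","wt","wt",,"wt",,"wt","wt",,"wt",0,115.011855707278,15.4078643576767,TRUE,6.53749275506367,TRUE
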