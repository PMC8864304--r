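group,cause,deaths_2000,deaths_2019
all,road_traffic,162355,115843
all,neoplasms,107826,95401
all,malaria,116250,81516
all,drowning,131420,77460
all,diarrhoea,144702,72679
all,tuberculosis,124546,70829
all,self_harm,68702,61903
all,lri,82132,58883
all,digestive,101716,56323
all,interpersonal_violence,55568,53540
all,cardiovascular,51261,38634
all,hiv,34351,33527
all,measles,57732,21759
all,collective_violence,18226,21034
all,congenital,19117,17555
all,maternal,18056,12167
all,natural_disasters,2270,992
all,other_cmpn,317199,218570
all,other_ncd,305954,215965
all,other_injuries,202328,155631
all,all_cause,2121733,1480227
5to9,diarrhoea,105893,51630
5to9,malaria,81802,49934
5to9,lri,51637,33851
5to9,drowning,53273,33086
5to9,neoplasms,30113,28449
5to9,road_traffic,41132,27989
5to9,tuberculosis,36710,22369
5to9,measles,57737,21764
5to9,congenital,19121,17556
5to9,digestive,40244,16124
5to9,hiv,19173,8349
5to9,collective_violence,3890,5082
5to9,natural_disasters,618,331
5to9,other_cmpn,134544,86965
5to9,other_ncd,115353,67718
5to9,other_injuries,79095,45778
5to9,all_cause,870327,516971
10to14,malaria,34455,31587
10to14,neoplasms,29796,26820
10to14,lri,30507,25034
10to14,drowning,48477,23610
10to14,road_traffic,34548,22542
10to14,diarrhoea,38815,21047
10to14,hiv,7092,12068
10to14,digestive,22184,10595
10to14,tuberculosis,11575,7823
10to14,collective_violence,4890,5835
10to14,natural_disasters,746,298
10to14,other_cmpn,77870,61919
10to14,other_ncd,92261,58396
10to14,other_injuries,57247,60572
10to14,all_cause,490461,368151
15to19f,self_harm,36989,32646
15to19f,neoplasms,21425,18298
15to19f,cardiovascular,25848,16953
15to19f,road_traffic,19697,16559
15to19f,tuberculosis,35496,15369
15to19f,digestive,20920,12937
15to19f,maternal,18047,12161
15to19f,interpersonal_violence,9097,10437
15to19f,hiv,5045,5949
15to19f,drowning,6725,4531
15to19f,collective_violence,3347,3315
15to19f,natural_disasters,321,129
15to19f,other_cmpn,53887,28460
15to19f,other_ncd,51472,47105
15to19f,other_injuries,25761,18373
15to19f,all_cause,334080,243225
15to19m,road_traffic,66979,48757
15to19m,interpersonal_violence,46464,43102
15to19m,self_harm,31720,29255
15to19m,tuberculosis,40769,25265
15to19m,neoplasms,26487,21834
15to19m,cardiovascular,25407,21686
15to19m,digestive,18364,16665
15to19m,drowning,22948,16239
15to19m,hiv,3044,7154
15to19m,collective_violence,6096,6795
15to19m,natural_disasters,593,232
15to19m,other_cmpn,50912,41237
15to19m,other_ncd,46861,42747
15to19m,other_injuries,40219,30913
15to19m,all_cause,426860,351881
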