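name,boiling_point_c,rt_mobile_min,area_mobile,match_factor,rt_td_min,area_td,origin_class
1-Propanol,95,1.00,320802296,937,2.78,86417340,pot endo
"Cyclohexane, methyl-",101,2.06,3895100,715,4.54,31159370,pot metab
Toluene,111,2.29,2896431,838,5.11,2264769,exo
"Heptane, 2-methyl-",118,2.35,851165,575,4.97,111756372,pot metab
Hexanal,128,2.45,5600184,735,5.38,2905761,pot endo
"Propanoic acid, propylester",122,2.57,1922248,745,5.91,272145,pot endo
Ethylbenzene,136,3.54,4087496,839,7.13,342180,exo
"Pyrazine, 2,5dimethyl-",155,4.38,71719045,854,8.05,75802,pot metab
Nonane,152,4.49,980197,606,8.40,275808,pot metab
"Benzene, (1methylethyl)-",152,5.02,1043167,687,8.69,6813,exo
Benzaldehyde,179,5.27,62440110,900,9.16,271986,pot metab
"5-Hepten-2-one, 6-methyl-",173,6.03,5492894,644,10.03,254562,pot metab
D-Limonene,175,7.04,44230737,887,11.50,107289,pot metab
Acetophenone,202,7.19,11704738,667,12.18,193246,exo
Nonanal,191,8.00,114615201,823,13.92,9186924,pot metab
Undecane,197,8.15,55673854,742,14.49,18506217,exo
Decanal,209,9.17,11160309,790,15.63,5270498,pot endo
Dodecane,216,9.24,8432826,716,15.99,2401000,pot endo
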