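"residue","nucleus","shift_ppm","intensity"
60,"HN",8.84838337885867,89.3204577426743
60,"N",120.452513645349,113.49317545686
60,"CA",59.212804969423,97.8998759836215
60,"CB",44.0691319846336,98.1246273418671
61,"HN",9.10736948555082,98.7535513504993
61,"N",124.219478616894,157.984869301746
61,"CA",53.833417896663,94.5768217311751
61,"CB",34.2000719816381,113.563285792273
62,"HN",8.18629883143357,58.7845521474447
62,"N",109.238132285698,130.215771476971
62,"CA",57.0800842177646,70.0289339781661
62,"CB",33.9684958654423,127.498567064129
63,"HN",9.05807738450599,91.7508140767883
63,"N",117.970922468924,70.2835355686219
63,"CA",59.3802920644938,87.9854280825867
63,"CB",37.7327007394473,115.138718980924
64,"HN",8.71404140878797,88.5338452321101
64,"N",121.019820493192,70.9353181732346
64,"CA",55.6466229748615,84.3511689439641
64,"CB",20.5147541003202,100.725068119246
65,"HN",8.3823994400801,93.0334146821055
65,"N",122.032652942798,86.4727400702227
65,"CA",53.8951568667421,109.042072191595
65,"CB",30.13164094288,133.485177048669
66,"HN",8.12742151895466,114.011550412341
66,"N",120.287701060816,85.4902554251701
66,"CA",62.7271825593759,113.721223673444
66,"CB",35.5385638795976,105.686835099579
67,"HN",8.57171552642211,101.812894721886
67,"N",107.027639667388,105.86310283006
67,"CA",56.8982960717771,103.774087305183
68,"HN",8.5327294909462,132.306017183923
68,"N",116.090831762102,129.758977758616
68,"CA",59.0075443592562,123.084536230688
69,"HN",8.66829142731626,115.508696160612
69,"N",114.827524245729,98.2124420707499
69,"CA",59.8705544859986,82.6376604634986
69,"CB",31.7430271125569,112.321970699423
70,"HN",8.60727149513384,109.719126371882
70,"N",115.456894810361,80.2553965323745
70,"CA",62.5381210294148,105.29379320647
70,"CB",35.5306413749575,97.6110670093806
71,"HN",7.82226844193579,113.02053926429
71,"N",118.131440617014,96.4108594069491
71,"CA",60.8000389857135,117.863221002234
71,"CB",43.3526982556056,90.9159452759708
72,"HN",8.56013942429052,132.077949824481
72,"N",114.556844482208,84.1845715417652
72,"CA",54.6047839574387,74.6885937289039
72,"CB",35.479895319447,113.955845582812
73,"HN",8.7803861502394,123.238364578237
73,"N",114.987165412641,144.729512068684
73,"CA",55.9996797737265,102.132700035194
73,"CB",32.4664647087869,97.5826929728529
74,"HN",8.3752772138006,102.411844779165
74,"N",118.89962979653,102.184983202422
74,"CA",56.54369429246,90.4074576252898
74,"CB",25.0334055205111,92.6383720320042
75,"HN",8.09493989684888,171.665597883872
75,"N",113.551535075241,102.783150063662
75,"CA",53.5191247980511,74.521154470349
75,"CB",35.748214317182,81.9281266802969
76,"HN",8.29927095427812,91.7913814932144
76,"N",116.545313574202,66.7019786169922
76,"CA",54.32575614892,103.655559451033
76,"CB",38.4057235665412,90.6127303962023
77,"HN",8.30002515362614,125.179425821628
77,"N",124.759422971905,80.2982182715103
77,"CA",57.6480413192495,127.163017559062
77,"CB",32.1816225166022,98.9560971852155
78,"HN",8.26555708070516,83.7331019349847
78,"N",117.221263980461,99.4128330212181
78,"CA",56.7583934528262,124.941720260265
78,"CB",32.1140429500761,91.7012838278337
79,"HN",8.57874503062084,80.9552476105717
79,"N",118.837206099395,73.3220382178007
79,"CA",61.501508647707,94.6741547383121
79,"CB",32.1929280519665,78.0632753600263
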