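"residue","nucleus","shift_ppm","intensity"
60,"HN",8.84830575852089,88.0163812483549
60,"N",120.44451082357,111.15862081889
60,"CA",59.2074700461235,104.59440943876
60,"CB",44.0820087370895,97.8907845232744
61,"HN",9.1056142268484,99.8413670458196
61,"N",124.208760793052,150.529886871818
61,"CA",53.8350499654877,91.078874689618
61,"CB",34.1964445974818,119.221621122906
62,"HN",8.19219896691344,62.5218109179601
62,"N",109.252456504975,138.427763341672
62,"CA",57.0701572926535,65.2790588350749
62,"CB",33.9730423684181,141.07487047659
63,"HN",9.05892636509277,96.4128823226891
63,"N",117.979878124747,70.1021938414769
63,"CA",59.3779942831043,91.0201764906965
63,"CB",37.7410669301319,109.546625976172
64,"HN",8.6965908501746,83.7103702192669
64,"N",121.036715082405,71.0206728716447
64,"CA",55.6552707546467,79.3487613257208
64,"CB",20.5132463404314,101.559139820171
65,"HN",8.36790936877871,99.1421900348403
65,"N",122.039083029798,82.0164108207922
65,"CA",53.8999888053803,104.960738211156
65,"CB",30.1315773866158,133.629192243392
66,"HN",8.12893607788329,108.224013007503
66,"N",120.281859971112,83.7638659974581
66,"CA",62.7308706267022,118.642188103691
66,"CB",35.5415104229948,110.794694403742
67,"HN",8.56892293268868,103.655062242653
67,"N",107.014277300839,96.3876745747842
67,"CA",56.9053035599615,103.365340449745
68,"HN",8.55827145716894,69.6809776019414
68,"N",116.282468696174,67.4858175625697
68,"CA",59.0915984776362,60.8822040641197
69,"HN",8.69034101312213,50.4023583286447
69,"N",115.024073365949,49.1945929129221
69,"CA",59.9730806030323,42.467521048417
69,"CB",31.810087087902,56.2194405545411
70,"HN",8.61767979069003,55.2237877277888
70,"N",115.667752558898,40.9512848574435
70,"CA",62.6421587784619,51.5495634246997
70,"CB",35.6165062503247,52.0421146356422
71,"HN",7.84042072639733,115.564187966972
71,"N",118.1327288313,90.4932870798095
71,"CA",60.7800296933362,126.129861741985
71,"CB",43.35603602758,96.4353002420785
72,"HN",8.57185267556411,137.458467626512
72,"N",114.577439874631,77.3765408864342
72,"CA",54.5910153414563,72.5032505175207
72,"CB",35.4683867637907,117.48591707552
73,"HN",8.7733279362918,123.353806178423
73,"N",114.97662485482,147.084592540449
73,"CA",55.9932223364951,115.344975788121
73,"CB",32.4646109291101,93.5558173414904
74,"HN",8.3832649932932,46.0170831056596
74,"N",119.1199995182,51.7314199618863
74,"CA",56.6447720399089,43.622486180023
74,"CB",25.1125644395061,47.3040517574388
75,"HN",8.09989609326493,164.630910539834
75,"N",113.551909227102,114.652604995855
75,"CA",53.5178039176816,73.9695231915264
75,"CB",35.7629821914176,79.8972984194936
76,"HN",8.2971006521772,90.9183711548403
76,"N",116.532477552161,69.5528870074952
76,"CA",54.3296128278245,104.031009253175
76,"CB",38.4022084378059,83.4390287115935
77,"HN",8.29480719269258,124.994380510687
77,"N",124.748741659898,83.30323426591
77,"CA",57.6523249782821,127.25204867366
77,"CB",32.1798823342579,102.530315521142
78,"HN",8.27071375799165,83.0187828870965
78,"N",117.218920327688,99.0020156309357
78,"CA",56.751808418568,127.830142405308
78,"CB",32.1265453161169,96.245684294827
79,"HN",8.57602739346973,75.9721773345299
79,"N",118.846685619354,73.108120654269
79,"CA",61.489492823406,94.2213414997617
79,"CB",32.1882668910027,75.0645891665754
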