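"freq_hz","magnitude_db"
0.05,-64.46645909
0.05197287327,-63.10704133
0.05402359112,-61.74650204
0.05615522509,-60.3847642
0.05837096794,-59.02174696
0.06067413839,-57.65736577
0.0630681861,-56.29153254
0.06555669687,-54.92415604
0.06814339797,-53.5551423
0.07083216373,-52.18439532
0.07362702138,-50.81181789
0.07653215703,-49.43731275
0.07955192196,-48.06078408
0.08269083917,-46.68213932
0.08595361009,-45.30129162
0.08934512169,-43.91816278
0.09287045373,-42.53268699
0.09653488644,-41.14481545
0.1003439084,-39.7545221
0.1043032247,-38.36181066
0.1084187655,-36.96672321
0.1126966952,-35.56935072
0.1171434212,-34.16984582
0.1217656037,-32.76843821
0.1265701658,-31.36545325
0.1315643037,-29.96133413
0.1367554977,-28.5566682
0.142151523,-27.15221798
0.1477604618,-25.74895715
0.1535907151,-24.348112
0.1596510154,-22.95120798
0.1659504398,-21.56012112
0.1724984235,-20.1771328
0.1793047741,-18.80498574
0.186379686,-17.44693744
0.193733756,-16.10680573
0.201377999,-14.78899929
0.2093238644,-13.49852409
0.2175832535,-12.24095539
0.2261685372,-11.0223649
0.2350925745,-9.849193988
0.2443687316,-8.72806804
0.2540109023,-7.665553195
0.2640335287,-6.667865298
0.2744516225,-5.740549906
0.2852807879,-4.888160335
0.2965372448,-4.113965841
0.3082378528,-3.419722823
0.3204001372,-2.805537633
0.3330423145,-2.269840314
0.3461833201,-1.809475369
0.3598428365,-1.419900364
0.3740413228,-1.095468759
0.3888000453,-0.8297629746
0.4041411096,-0.6159398591
0.4200874935,-0.4470539838
0.4366630812,-0.3163329808
0.4538926996,-0.2173906068
0.4718021551,-0.1443742812
0.4904182723,-0.092052412
0.5097689343,-0.055852021
0.5298831243,-0.03185925416
0.5507909694,-0.01679511077
0.572523785,-0.007977116963
0.5951141224,-0.003275498477
0.6185958173,-0.001070225806
0.6430040403,-0.0002134069456
0.66837535,0
0.6947477472,-0.0001487002245
0.7221607324,-0.0007940511109
0.7506553645,-0.002490234569
0.7802743225,-0.006226498512
0.8110619696,-0.01345366519
0.8430644191,-0.02612051309
0.8763296043,-0.04671792228
0.9109073493,-0.07832740881
0.9468494445,-0.1246689667
0.9842097236,-0.1901409679
1.023044145,-0.2798423486
1.063410874,-0.3995647421
1.105370371,-0.5557402052
1.148985485,-0.7553296509
1.194321539,-1.005639246
1.24144644,-1.314058061
1.29043077,-1.687720816
1.341347898,-2.133114187
1.394274086,-2.655661324
1.449288607,-3.259332888
1.506473862,-3.94633887
1.565915503,-4.716949673
1.627702559,-5.569476888
1.691927577,-6.500417556
1.75868675,-7.50473781
1.828080072,-8.57625054
1.900211478,-9.708032266
1.975189007,-10.89282755
2.053124959,-12.12340169
2.134136066,-13.39281894
2.218343665,-14.69463931
2.305873884,-16.02303882
2.396857823,-17.37286559
2.491431757,-18.73964645
2.58973734,-20.11955921
2.691921811,-21.5093832
2.798138223,-22.90643827
2.908545665,-24.30851955
3.023309505,-25.71383307
3.142601635,-27.12093516
3.26660073,-28.5286775
3.395492515,-29.93615839
3.529470043,-31.3426804
3.668733985,-32.747714
3.81349293,-34.15086682
3.963963695,-35.55185773
4.120371655,-36.95049523
4.282951077,-38.34665955
4.451945471,-39.74028785
4.627607955,-41.13136205
4.810201636,-42.51989888
5,-43.90594179
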