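! 6-31G(d,p) split-valence polarized basis set (Pople and co-workers).
! Cartesian (6d) polarization functions.  Same file format as 3-21g.txt.
element H
S 3
18.7311370 0.03349460
2.8253937 0.23472695
0.6401217 0.81375733
S 1
0.1612778 1.0
P 1
1.1000000 1.0
end
element He
S 3
38.4216340 0.0401397
5.7780300 0.2612461
1.2417740 0.7931846
S 1
0.2979640 1.0
P 1
1.1000000 1.0
end
element Li
S 6
642.418920 0.0021426
96.7985150 0.0162089
22.0911210 0.0773156
6.2010703 0.2457860
1.9351177 0.4701890
0.6367358 0.3454708
SP 3
2.3249184 -0.0350917 0.0089415
0.6324306 -0.1912328 0.1410095
0.0790534 1.0839878 0.9453637
SP 1
0.0359620 1.0 1.0
D 1
0.2000000 1.0
end
element C
S 6
3047.524900 0.0018347
457.3695100 0.0140373
103.9486900 0.0688426
29.2101550 0.2321844
9.2866630 0.4679413
3.1639270 0.3623120
SP 3
7.8682724 -0.1193324 0.0689991
1.8812885 -0.1608542 0.3164240
0.5442493 1.1434564 0.7443083
SP 1
0.1687144 1.0 1.0
D 1
0.8000000 1.0
end
element N
S 6
4173.5110000 0.0018348
627.4579000 0.0139950
142.9021000 0.0685870
40.2343300 0.2322410
12.8202100 0.4690700
4.3904370 0.3604550
SP 3
11.6263580 -0.1149610 0.0675800
2.7162800 -0.1691180 0.3239070
0.7722180 1.1458520 0.7408950
SP 1
0.2120313 1.0 1.0
D 1
0.8000000 1.0
end
element O
S 6
5484.6717000 0.0018311
825.2349500 0.0139501
188.0469600 0.0684451
52.9645000 0.2327143
16.8975700 0.4701930
5.7996353 0.3585209
SP 3
15.5396160 -0.1107775 0.0708743
3.5999336 -0.1480263 0.3397528
1.0137618 1.1307670 0.7271586
SP 1
0.2700058 1.0 1.0
D 1
0.8000000 1.0
end
element F
S 6
7001.7131000 0.0018196
1051.3660000 0.0139161
239.2856900 0.0684053
67.3974530 0.2331858
21.5195570 0.4712674
7.4031013 0.3566185
SP 3
20.8479520 -0.1085070 0.0716287
4.8083083 -0.1464517 0.3459121
1.3440699 1.1286886 0.7224700
SP 1
0.3581514 1.0 1.0
D 1
0.8000000 1.0
end
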