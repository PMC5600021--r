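! 3-21G split-valence basis set (Pople and co-workers).
! Format: "element <symbol>", then shells as "<S|P|D|SP> <nprim>" followed by
! nprim lines of exponent and contraction coefficient(s); "end" closes the
! element.  Coefficients refer to normalized primitives.
element H
S 2
5.447178 0.156285
0.824547 0.904691
S 1
0.183192 1.0
end
element He
S 2
13.62670 0.175230
1.999350 0.893483
S 1
0.382993 1.0
end
element Li
S 3
36.8382 0.0696686
5.48172 0.381346
1.11327 0.681702
SP 2
0.540205 -0.263127 0.161546
0.102255 1.143390 0.915663
SP 1
0.0285645 1.0 1.0
end
element Be
S 3
71.8876 0.0644263
10.7289 0.366096
2.22205 0.695934
SP 2
1.295480 -0.421064 0.205132
0.268881 1.224070 0.882528
SP 1
0.077350 1.0 1.0
end
element B
S 3
116.434 0.0629605
17.4314 0.363304
3.68016 0.697255
SP 2
2.281870 -0.368662 0.231152
0.465248 1.199440 0.866764
SP 1
0.124328 1.0 1.0
end
element C
S 3
172.256 0.0617669
25.9109 0.358794
5.53335 0.700713
SP 2
3.664980 -0.395897 0.236460
0.770545 1.215840 0.860619
SP 1
0.195857 1.0 1.0
end
element N
S 3
242.766 0.0598657
36.4851 0.352955
7.81449 0.700130
SP 2
5.425220 -0.413301 0.237972
1.149150 1.224420 0.858953
SP 1
0.283205 1.0 1.0
end
element O
S 3
322.037 0.0592394
48.4308 0.351500
10.4206 0.707658
SP 2
7.402940 -0.404453 0.244586
1.576200 1.221560 0.853955
SP 1
0.373684 1.0 1.0
end
element F
S 3
413.801 0.0585483
62.2446 0.349308
13.4340 0.709632
SP 2
9.777590 -0.407327 0.246680
2.086170 1.223140 0.852321
SP 1
0.482383 1.0 1.0
end
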