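topic	forum_n	facebook_n
1	978	3294
2	590	3925
3	1147	3785
4	860	4065
5	1315	2804
6	759	3715
7	810	3014
8	523	3084
9	877	3645
10	692	3505
11	675	2804
12	523	2734
13	1113	5047
14	692	3014
15	843	2804
16	1063	2734
17	1248	3575
18	540	5607
19	1198	3432
20	422	3505
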