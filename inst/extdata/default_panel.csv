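position,pool
255,1
905,1
970,1
1364,1
1586,1
1648,1
1773,1
1835,1
1932,1
2036,1
2043,1
2161,1
2231,1
2301,1
2434,1
2452,1
2461,1
2519,1
2533,1
2556,1
2706,1
2840,1
3282,1
3326,2
3515,2
3520,2
4027,2
4158,2
4204,2
4303,2
4383,2
4395,2
4476,2
4651,2
4943,2
5046,2
5244,2
5341,2
5480,2
5513,2
5904,2
5917,2
6076,2
6379,2
6520,2
6778,2
7028,2
7058,2
7085,2
7120,2
7438,2
7773,2
8190,2
8372,2
8405,2
8431,2
8437,2
8701,2
8793,2
9055,3
9135,3
9147,3
9151,3
9384,3
9397,3
9617,3
9876,3
10121,3
10348,3
10400,3
10451,3
10520,3
10551,3
10743,3
10850,3
10873,3
10901,3
11056,3
11389,3
11467,3
11636,3
11649,3
11660,3
11762,3
11796,3
11812,3
11851,3
12047,3
12224,3
12232,3
12284,4
12308,4
12705,4
12960,4
12980,4
13242,4
13368,4
13403,4
13477,4
13549,4
13691,4
13739,4
13779,4
13969,4
14508,4
14523,4
14536,4
14679,4
14783,4
15043,4
15306,4
15501,4
15503,4
16095,4
16383,4
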