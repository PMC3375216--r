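day,count,sd
0,107.8,8
0.48,110.2,9.8
0.96,188.9,14.5
1.44,219.3,19.8
1.92,372.6,28.6
2.4,547.6,40.1
2.88,644.7,50.3
3.36,943.7,62.1
3.84,979.4,76.9
4.32,1103.8,84.4
4.8,1398.8,97.7
5.28,1532.6,109.5
5.76,1324.8,121.3
6.24,1757.8,137.4
6.72,1975.4,159.7
7.2,1857.7,176.5
7.68,2812,198.7
8.16,2762.2,216.7
8.64,2627.8,230.2
9.12,3059.7,252.6
9.6,3357.9,267
10.08,3906.2,282.2
10.56,4270.9,303.6
11.04,4276.2,329.2
11.52,3918.9,346.1
12,5124.7,362.2
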