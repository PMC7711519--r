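# customer waiting times before service, bank B (minutes), one value per line
0.1
0.2
0.3
0.7
0.9
1.1
1.2
1.8
1.9
2.0
2.2
2.3
2.3
2.3
2.5
2.6
2.7
2.7
2.9
3.1
3.1
3.2
3.4
3.4
3.5
3.9
4.0
4.2
4.5
4.7
5.3
5.6
5.6
6.2
6.3
6.6
6.8
7.3
7.5
7.7
7.7
8.0
8.0
8.5
8.5
8.7
9.5
10.7
10.9
11.0
12.1
12.3
12.8
12.9
13.2
13.7
14.5
16.0
16.5
28.0
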