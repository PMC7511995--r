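# Zachary's karate club, weighted (strength of association, 1-8)
1 2 4
1 3 5
1 4 3
1 5 3
1 6 3
1 7 3
1 8 2
1 9 2
1 11 2
1 12 3
1 13 1
1 14 3
1 18 2
1 20 2
1 22 2
1 32 2
2 3 6
2 4 3
2 8 4
2 14 5
2 18 1
2 20 2
2 22 2
2 31 2
3 4 3
3 8 4
3 9 5
3 10 1
3 14 3
3 28 2
3 29 2
3 33 2
4 8 3
4 13 3
4 14 3
5 7 2
5 11 3
6 7 5
6 11 3
6 17 3
7 17 3
9 31 3
9 33 3
9 34 4
10 34 2
14 34 3
15 33 3
15 34 2
16 33 3
16 34 4
19 33 1
19 34 2
20 34 1
21 33 3
21 34 1
23 33 2
23 34 3
24 26 5
24 28 4
24 30 3
24 33 5
24 34 4
25 26 2
25 28 3
25 32 2
26 32 7
27 30 4
27 34 2
28 34 4
29 32 2
29 34 2
30 33 4
30 34 2
31 33 3
31 34 3
32 33 4
32 34 4
33 34 5
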