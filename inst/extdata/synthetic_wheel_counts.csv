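time_h,value
0,4
0.25,6
0.5,6
0.75,4
1,6
1.25,4
1.5,4
1.75,8
2,2
2.25,8
2.5,9
2.75,6
3,5
3.25,4
3.5,7
3.75,2
4,7
4.25,2
4.5,3
4.75,1
5,2
5.25,5
5.5,6
5.75,6
6,3
6.25,4
6.5,6
6.75,0
7,0
7.25,3
7.5,2
7.75,2
8,7
8.25,4
8.5,4
8.75,0
9,6
9.25,0
9.5,3
9.75,4
10,4
10.25,2
10.5,1
10.75,3
11,1
11.25,1
11.5,1
11.75,2
12,2
12.25,0
12.5,2
12.75,1
13,1
13.25,2
13.5,1
13.75,0
14,0
14.25,1
14.5,0
14.75,0
15,1
15.25,1
15.5,1
15.75,0
16,2
16.25,3
16.5,2
16.75,1
17,1
17.25,2
17.5,0
17.75,2
18,1
18.25,1
18.5,3
18.75,1
19,0
19.25,3
19.5,1
19.75,1
20,2
20.25,3
20.5,0
20.75,4
21,3
21.25,7
21.5,2
21.75,1
22,6
22.25,4
22.5,7
22.75,5
23,1
23.25,6
23.5,2
23.75,6
24,4
24.25,9
24.5,5
24.75,3
25,6
25.25,3
25.5,5
25.75,3
26,7
26.25,3
26.5,2
26.75,3
27,7
27.25,2
27.5,5
27.75,7
28,2
28.25,4
28.5,8
28.75,7
29,3
29.25,4
29.5,3
29.75,8
30,1
30.25,6
30.5,2
30.75,5
31,0
31.25,4
31.5,5
31.75,7
32,9
32.25,3
32.5,0
32.75,0
33,2
33.25,4
33.5,3
33.75,3
34,0
34.25,0
34.5,2
34.75,4
35,1
35.25,0
35.5,1
35.75,2
36,5
36.25,1
36.5,1
36.75,1
37,1
37.25,1
37.5,1
37.75,3
38,0
38.25,2
38.5,1
38.75,0
39,0
39.25,1
39.5,0
39.75,0
40,2
40.25,2
40.5,0
40.75,2
41,2
41.25,0
41.5,2
41.75,2
42,1
42.25,3
42.5,2
42.75,1
43,3
43.25,2
43.5,3
43.75,2
44,0
44.25,4
44.5,3
44.75,1
45,6
45.25,2
45.5,4
45.75,2
46,9
46.25,5
46.5,5
46.75,5
47,2
47.25,1
47.5,1
47.75,2
48,2
48.25,2
48.5,1
48.75,4
49,4
49.25,7
49.5,8
49.75,10
50,1
50.25,6
50.5,2
50.75,7
51,1
51.25,5
51.5,4
51.75,2
52,7
52.25,6
52.5,8
52.75,4
53,4
53.25,7
53.5,4
53.75,3
54,6
54.25,2
54.5,2
54.75,2
55,4
55.25,6
55.5,4
55.75,2
56,6
56.25,3
56.5,7
56.75,2
57,3
57.25,0
57.5,1
57.75,6
58,2
58.25,3
58.5,5
58.75,2
59,1
59.25,3
59.5,4
59.75,1
60,0
60.25,1
60.5,1
60.75,0
61,0
61.25,1
61.5,2
61.75,0
62,2
62.25,1
62.5,0
62.75,0
63,1
63.25,0
63.5,1
63.75,0
64,0
64.25,1
64.5,0
64.75,0
65,0
65.25,1
65.5,2
65.75,1
66,2
66.25,1
66.5,0
66.75,4
67,5
67.25,1
67.5,0
67.75,0
68,0
68.25,3
68.5,2
68.75,3
69,1
69.25,2
69.5,7
69.75,4
70,3
70.25,1
70.5,4
70.75,2
71,3
71.25,8
71.5,9
71.75,6
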