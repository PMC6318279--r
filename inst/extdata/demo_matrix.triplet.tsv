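0	0	24
0	1	19
0	2	22
0	3	17
0	4	23
0	5	25
0	6	20
0	7	15
0	8	16
0	9	20
0	10	18
0	11	23
0	12	19
0	13	20
0	14	22
0	15	22
0	16	23
0	17	20
0	18	21
0	19	20
0	20	20
0	21	19
0	22	20
0	23	17
0	24	17
0	25	16
0	26	19
0	27	22
0	28	24
0	29	27
1	1	21
1	2	20
1	3	23
1	4	14
1	5	18
1	6	25
1	7	26
1	8	19
1	9	20
1	10	22
1	11	16
1	12	20
1	13	15
1	14	21
1	15	22
1	16	26
1	17	23
1	18	19
1	19	19
1	20	24
1	21	23
1	22	17
1	23	20
1	24	14
1	25	20
1	26	15
1	27	23
1	28	16
1	29	19
2	2	15
2	3	16
2	4	27
2	5	20
2	6	16
2	7	16
2	8	21
2	9	21
2	10	21
2	11	12
2	12	15
2	13	20
2	14	26
2	15	21
2	16	21
2	17	16
2	18	23
2	19	24
2	20	18
2	21	22
2	22	20
2	23	21
2	24	19
2	25	13
2	26	22
2	27	23
2	28	22
2	29	18
3	3	24
3	4	18
3	5	16
3	6	16
3	7	19
3	8	22
3	9	13
3	10	15
3	11	16
3	12	16
3	13	20
3	14	21
3	15	19
3	16	18
3	17	21
3	18	20
3	19	19
3	20	18
3	21	19
3	22	20
3	23	23
3	24	14
3	25	26
3	26	22
3	27	17
3	28	20
3	29	16
4	4	13
4	5	18
4	6	24
4	7	21
4	8	13
4	9	25
4	10	16
4	11	19
4	12	21
4	13	19
4	14	23
4	15	24
4	16	20
4	17	23
4	18	18
4	19	17
4	20	19
4	21	19
4	22	24
4	23	18
4	24	16
4	25	21
4	26	21
4	27	18
4	28	15
4	29	26
5	5	19
5	6	19
5	7	22
5	8	14
5	9	17
5	10	24
5	11	15
5	12	24
5	13	24
5	14	14
5	15	19
5	16	19
5	17	19
5	18	23
5	19	22
5	20	12
5	21	20
5	22	29
5	23	30
5	24	17
5	25	17
5	26	19
5	27	20
5	28	20
5	29	17
6	6	22
6	7	24
6	8	22
6	9	19
6	10	18
6	11	20
6	12	20
6	13	17
6	14	16
6	15	21
6	16	21
6	17	23
6	18	20
6	19	15
6	20	19
6	21	23
6	22	22
6	23	24
6	24	25
6	25	22
6	26	22
6	27	20
6	28	19
6	29	21
7	7	20
7	8	19
7	9	17
7	10	16
7	11	23
7	12	21
7	13	18
7	14	17
7	15	18
7	16	21
7	17	16
7	18	20
7	19	23
7	20	23
7	21	17
7	22	22
7	23	15
7	24	20
7	25	17
7	26	15
7	27	23
7	28	16
7	29	16
8	8	23
8	9	21
8	10	20
8	11	21
8	12	22
8	13	20
8	14	19
8	15	20
8	16	21
8	17	20
8	18	27
8	19	25
8	20	20
8	21	22
8	22	18
8	23	16
8	24	23
8	25	16
8	26	17
8	27	20
8	28	20
8	29	14
9	9	17
9	10	19
9	11	19
9	12	18
9	13	21
9	14	15
9	15	18
9	16	22
9	17	18
9	18	21
9	19	23
9	20	19
9	21	17
9	22	22
9	23	18
9	24	22
9	25	19
9	26	19
9	27	20
9	28	18
9	29	20
10	10	17
10	11	18
10	12	19
10	13	19
10	14	20
10	15	19
10	16	20
10	17	18
10	18	14
10	19	17
10	20	19
10	21	19
10	22	21
10	23	16
10	24	15
10	25	17
10	26	17
10	27	18
10	28	18
10	29	17
11	11	23
11	12	24
11	13	21
11	14	15
11	15	17
11	16	19
11	17	15
11	18	22
11	19	20
11	20	16
11	21	24
11	22	23
11	23	15
11	24	18
11	25	20
11	26	20
11	27	15
11	28	20
11	29	23
12	12	16
12	13	14
12	14	15
12	15	20
12	16	20
12	17	17
12	18	23
12	19	24
12	20	18
12	21	16
12	22	23
12	23	20
12	24	24
12	25	15
12	26	16
12	27	23
12	28	22
12	29	17
13	13	18
13	14	18
13	15	14
13	16	22
13	17	24
13	18	16
13	19	15
13	20	17
13	21	22
13	22	21
13	23	21
13	24	20
13	25	23
13	26	14
13	27	23
13	28	17
13	29	24
14	14	11
14	15	20
14	16	21
14	17	20
14	18	18
14	19	18
14	20	15
14	21	18
14	22	19
14	23	18
14	24	22
14	25	17
14	26	17
14	27	17
14	28	16
14	29	18
15	15	22
15	16	26
15	17	21
15	18	18
15	19	20
15	20	16
15	21	21
15	22	19
15	23	16
15	24	20
15	25	22
15	26	21
15	27	21
15	28	22
15	29	21
16	16	22
16	17	20
16	18	13
16	19	22
16	20	24
16	21	19
16	22	23
16	23	19
16	24	18
16	25	16
16	26	17
16	27	23
16	28	14
16	29	14
17	17	14
17	18	25
17	19	17
17	20	17
17	21	21
17	22	20
17	23	17
17	24	18
17	25	18
17	26	15
17	27	18
17	28	21
17	29	20
18	18	19
18	19	20
18	20	21
18	21	23
18	22	19
18	23	15
18	24	21
18	25	15
18	26	22
18	27	22
18	28	19
18	29	28
19	19	19
19	20	16
19	21	19
19	22	18
19	23	19
19	24	20
19	25	20
19	26	13
19	27	18
19	28	17
19	29	22
20	20	22
20	21	19
20	22	19
20	23	21
20	24	18
20	25	18
20	26	15
20	27	23
20	28	19
20	29	21
21	21	23
21	22	21
21	23	18
21	24	16
21	25	21
21	26	16
21	27	18
21	28	24
21	29	23
22	22	21
22	23	20
22	24	19
22	25	25
22	26	23
22	27	18
22	28	15
22	29	21
23	23	25
23	24	22
23	25	26
23	26	17
23	27	24
23	28	19
23	29	19
24	24	22
24	25	25
24	26	21
24	27	20
24	28	18
24	29	21
25	25	20
25	26	18
25	27	26
25	28	18
25	29	23
26	26	12
26	27	20
26	28	15
26	29	24
27	27	21
27	28	20
27	29	16
28	28	24
28	29	21
29	29	27
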