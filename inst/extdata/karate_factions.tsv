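# Zachary karate club: the two observed factions
1	instructor
2	instructor
3	instructor
4	instructor
5	instructor
6	instructor
7	instructor
8	instructor
9	administrator
10	administrator
11	instructor
12	instructor
13	instructor
14	instructor
15	administrator
16	administrator
17	instructor
18	instructor
19	administrator
20	instructor
21	administrator
22	instructor
23	administrator
24	administrator
25	administrator
26	administrator
27	administrator
28	administrator
29	administrator
30	administrator
31	administrator
32	administrator
33	administrator
34	administrator
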