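m	pdb_id	rg
1	1PRW	14.60
2	3EWT	15.17
3	2LGF	15.23
4	3DVJ	15.31
5	3BYA	15.38
6	2LHI	15.38
7	2HQW	15.41
8	2L7L	15.43
9	3EWV	15.52
10	1IWQ	15.57
11	1L7Q	15.59
12	3DVE	15.61
13	1CDM	15.66
14	3SUI	15.68
15	3BXL	15.80
16	1IQ5	15.90
17	1ZUZ	15.93
18	3HR4	15.94
19	2KOF	15.95
20	2LL6	15.95
21	3GP2	15.96
22	3DVM	16.00
23	1CKK	16.05
24	2FOT	16.05
25	2JZI	16.12
26	1CM1	16.20
27	3DVK	16.22
28	2VAY	16.26
29	2O60	16.28
30	2WEL	16.35
31	1QTX	16.43
32	2O5G	16.47
33	1QS7	16.50
34	3GOF	16.50
35	3BXK	16.51
36	1MXE	16.55
37	2Y4V	16.62
38	2BE6	16.65
39	2F3Y	16.68
40	1SY9	16.83
41	2BBM	17.03
42	2BCX	17.25
43	2KNE	18.67
44	4DCK	18.87
45	1SK6	19.30
46	1XFU	19.31
47	2L1W	19.46
48	1K9O	19.46
49	1PKO	19.49
50	1S26	19.50
51	1LVC	19.70
52	1CFF	19.78
53	4G27	20.79
54	2L53	21.00
55	2KDU	25.65
56	4EHQ	22.07
57	4DJC	22.31
58	2YGG	23.66
59	1G4Y	25.32
60	1CLL	21.80
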