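#provenance=synthetic fixture: three-group T-cell-epitope classification following the field-standard exon-2 family split
#coordinate=mature
allele	group
02:01	3
02:02	3
04:01	3
04:02	3
17:01	1
23:01	3
30:01	3
39:01	3
40:01	3
49:01	3
55:01	3
106:01	3
126:01	3
133:01	3
138:01	3
535:01	3
907:01	3
01:01	2
03:01	2
05:01	2
06:01	2
09:01	1
10:01	1
11:01	2
13:01	2
14:01	2
15:01	2
16:01	2
18:01	2
19:01	2
20:01	2
21:01	2
29:01	2
35:01	2
36:01	2
45:01	2
85:01	2
90:01	3
100:01	3
104:01	2
131:01	2
350:01	3
417:01	3
519:01	2
99:99	2
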