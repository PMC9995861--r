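#provenance=published DP pocket residue table (crystal-structure derived, taken as data)
#coordinate=mature
pocket	chain	position
P1	alpha	24
P1	alpha	31
P1	alpha	32
P1	alpha	43
P1	alpha	52
P1	alpha	53
P1	alpha	54
P1	alpha	55
P1	beta	80
P1	beta	83
P1	beta	84
P2	alpha	9
P2	beta	76
P2	beta	79
P2	beta	80
P3	alpha	22
P3	alpha	54
P3	alpha	58
P4	alpha	9
P4	alpha	62
P4	beta	13
P4	beta	24
P4	beta	26
P4	beta	68
P4	beta	69
P4	beta	72
P4	beta	76
P5	beta	69
P6	alpha	11
P6	alpha	62
P6	alpha	65
P6	alpha	66
P6	beta	11
P6	beta	13
P6	beta	26
P6	beta	28
P7	alpha	65
P7	alpha	69
P7	beta	26
P7	beta	28
P7	beta	45
P7	beta	59
P7	beta	65
P7	beta	68
P7	beta	69
P8	alpha	65
P8	alpha	68
P8	alpha	69
P9	alpha	69
P9	alpha	72
P9	alpha	73
P9	alpha	76
P9	beta	9
P9	beta	28
P9	beta	35
P9	beta	36
P9	beta	55
P9	beta	59
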