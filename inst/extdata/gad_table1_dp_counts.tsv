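#provenance=printed DP allele chromosome counts and frequencies from the study's cohort frequency table
allele	ctrl_n	ctrl_af	case_n	case_af
DPA1*01:03	517	0.72	496	0.59
DPA1*02:01	127	0.18	207	0.24
DPA1*02:02	40	0.06	84	0.1
DPA1*03:01	14	0.02	34	0.04
DPB1*01:01	91	0.13	126	0.15
DPB1*02:01	95	0.13	98	0.12
DPB1*03:01	66	0.09	72	0.09
DPB1*04:01	254	0.35	197	0.23
DPB1*04:02	81	0.11	92	0.11
DPB1*17:01	18	0.02	37	0.04
DPB1*18:01	10	0.01	13	0.02
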