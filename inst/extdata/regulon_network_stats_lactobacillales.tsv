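genome	lineage	tfs	target_genes	target_operons	interactions
L. lactis cremoris SK11	Streptococcaceae	36	255	125	130
L. lactis lactis Il1403	Streptococcaceae	34	244	128	138
S. thermophilus CNRZ1066	Streptococcaceae	30	263	125	141
S. agalactiae 2603 V/R	Streptococcaceae	38	340	159	186
S. uberis 0140 J	Streptococcaceae	42	330	156	183
S. equi MGCS10565	Streptococcaceae	42	334	143	167
S. dysgalactiae GGS_124	Streptococcaceae	43	356	160	189
S. pyogenes M1 GAS	Streptococcaceae	40	319	150	180
S. gallolyticus UCN34	Streptococcaceae	41	328	167	199
S. mutans UA159	Streptococcaceae	41	317	147	173
S. suis 05ZYH33	Streptococcaceae	43	366	145	173
S. mitis B6	Streptococcaceae	35	305	148	174
S. pneumoniae TIGR4	Streptococcaceae	42	365	167	206
S. gordonii CH1	Streptococcaceae	41	312	167	194
S. sanguinis SK36	Streptococcaceae	43	339	163	191
L. sakei 23 K	Lactobacillaceae	36	186	92	106
L. casei ATCC 334	Lactobacillaceae	41	226	110	120
L. rhamnosus GG	Lactobacillaceae	42	237	106	116
L. delbrueckii ATCC BAA-365	Lactobacillaceae	18	69	36	37
L. acidophilus NCFM	Lactobacillaceae	27	165	80	90
L. helveticus DPC 4571	Lactobacillaceae	21	91	53	55
L. johnsonii NCC 533	Lactobacillaceae	26	145	78	87
P. pentosaceus ATCC 25745	Lactobacillaceae	38	205	97	111
L. brevis ATCC 367	Lactobacillaceae	39	217	112	128
L. plantarum WCFS1	Lactobacillaceae	46	299	147	170
L. fermentum IFO 3956	Lactobacillaceae	30	172	85	101
L. reuteri JCM 1112	Lactobacillaceae	32	167	83	96
O. oeni PSU-1	Lactobacillaceae	25	109	59	70
L. mesenteroides ATCC 8293	Lactobacillaceae	32	202	89	103
L. salivarius UCC118	Lactobacillaceae	31	198	86	96
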