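gene_id	degree	closeness	betweenness	p_value	fc	direction
ACTL6B	2	2.69	1.37	0.04	0.82	down
CRK	5	2.71	7.99	0.02	1.52	up
GHR	3	2.69	1.37	0.03	1.25	up
GRAPL	3	2.73	12.48	0.02	1.59	up
IGF1	4	2.69	1.43	0.02	0.81	down
MX1	5	2.72	11.21	0.02	0.55	down
OASL	5	2.70	5.02	0.01	0.62	down
RAB28	2	2.69	2.64	0.02	1.22	up
RAB33B	2	2.66	1.37	0.02	1.24	up
RNF2	3	2.68	2.64	0.02	1.65	up
RNF8	2	2.66	1.37	0.04	0.80	down
RPL23	3	2.67	1.37	0.04	0.79	down
SPINK1	3	2.71	6.66	0.02	0.63	down
UST	3	2.68	2.64	0.04	1.23	up
VAV2	2	2.68	1.37	0.03	1.21	up
ZNF384	2	2.66	1.37	0.01	1.23	up
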