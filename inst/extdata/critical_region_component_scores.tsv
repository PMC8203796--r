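gene	component1	Dminus	Dplus	Dremov	rank
DYRK1A	0.1195	1.69	1.03	1.30	10
DSCR3	0.1193	1.70	1.12	1.27	10
HLCS	0.1188	1.62	0.88	1.11	10
MORC3	0.1067	1.29	0.88	1.05	25
PIGP	0.1044	1.55	1.09	1.24	31
CBR3	0.1004	2.24	1.52	1.51	36
SETD4	0.0951	1.32	1.00	1.03	44
TTC3	0.0910	1.33	0.64	0.96	NA
CHAF1B	0.0859	1.76	1.03	1.03	NA
CBR3-AS1	0.0729	1.65	0.80	1.21	NA
LOC100506403	0.0687	1.04	1.00	1.00	NA
LINC00114	0.0687	1.04	1.00	1.00	NA
RUNX1	0.0662	1.41	0.63	0.98	NA
KCNJ15	0.0629	0.76	0.80	0.77	NA
CBR1	0.0521	0.55	0.47	0.43	NA
DOPEY2	0.0432	1.13	0.60	0.80	NA
SIM2	0.0389	2.96	1.60	2.27	NA
KCNJ6	0.0298	0.87	0.27	0.65	NA
DSCR9	0.0074	1.00	0.82	0.64	NA
LOC100133286	0.0053	1.00	1.07	1.10	NA
ERG	0.0049	1.03	1.25	1.40	NA
ETS2	0.0045	0.90	0.69	0.63	NA
RIPPLY3	0.0025	1.03	0.93	1.09	NA
RUNX1-IT1	0.0012	1.00	1.04	1.24	NA
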