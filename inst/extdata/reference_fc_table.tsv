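id	logFC	FC	ave
miR-628-3p	1.64	3.1	10.28
miR-30b*	1.44	2.7	11.41
miR-490-5p	1.37	2.6	9.59
miR-155	1.36	2.6	9.9
miR-553	1.29	2.4	9.48
miR-659	1.26	2.4	11.44
miR-516b	1.24	2.4	9.76
miR-500*	1.24	2.4	10.03
miR-483-5p	1.15	2.2	11.56
miR-198	1.06	2.1	10.28
miR-200b*	1.05	2.1	9.86
miR-768-5p	0.96	1.9	9.68
miR-411	0.95	1.9	8.58
miR-192	0.95	1.9	9.61
miR-450a	0.91	1.9	8.24
miR-625	0.89	1.9	9.75
miR-500	0.84	1.8	9.5
miR-615-3p	0.83	1.8	10.89
miR-770-5p	0.81	1.8	8.15
miR-371-5p	0.81	1.8	11.71
miR-125b-1*	0.72	1.6	10.41
miR-645	0.71	1.6	9.1
miR-654-5p	0.71	1.6	9.94
miR-552	0.7	1.6	9.91
miR-28-3p	0.69	1.6	9.36
miR-7	0.66	1.6	8.88
miR-126	0.64	1.6	8.5
miR-518c*	0.63	1.5	11.38
miR-885-5p	0.63	1.5	8.84
miR-548a-5p	0.61	1.5	9.13
miR-425*	0.61	1.5	8.97
miR-27a*	0.58	1.5	8.76
miR-331-5p	0.57	1.5	8.77
miR-99b*	0.53	1.4	9.88
miR-549	0.51	1.4	8.53
miR-576-3p	0.49	1.4	8.49
miR-373*	0.47	1.4	8.49
miR-125a-3p	0.44	1.4	8.62
miR-548a-3p	-0.46	-1.4	8.33
miR-200a*	-0.52	-1.4	9.6
miR-372	-0.54	-1.5	9.15
miR-148a*	-0.55	-1.5	9.15
miR-370	-0.55	-1.5	12.87
miR-29a*	-0.69	-1.6	8.78
miR-487b	-0.75	-1.7	10.41
miR-605	-0.78	-1.7	10.5
miR-634	-0.79	-1.7	10.21
let-7g	-0.85	-1.8	9.79
miR-29c*	-0.87	-1.8	9.12
miR-487a	-0.91	-1.9	10.46
miR-302b	-0.94	-1.9	10.74
miR-30b	-0.97	-2	10.7
miR-30d	-0.97	-2	9.85
miR-374a	-1	-2	9.22
let-7i	-1.03	-2	10.14
miR-148b	-1.07	-2.1	10.62
miR-30a	-1.11	-2.2	10.51
miR-195	-1.14	-2.2	10.35
miR-519d	-1.15	-2.2	11.7
miR-24	-1.22	-2.3	10.32
let-7f	-1.24	-2.4	10.02
miR-26a	-1.36	-2.6	11.13
miR-148a	-1.51	-2.8	12.3
miR-29b	-1.89	-3.7	12.95
miR-29c	-1.93	-3.8	12.14
miR-29a	-2.17	-4.5	12.48
miR-142-3p	-2.2	-4.6	12.05
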