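subject_id	r_ml	r_ap	r_v	s_ml	s_ap	s_v	group	kl_grade
Subject 1	0.40	0.41	0.93	0.61	0.65	0.97	Group1	3
Subject 2	0.35	0.44	0.93	0.61	0.64	0.94	Group1	3
Subject 3	0.21	0.40	0.95	0.63	0.64	0.92	Group1	3
Subject 4	0.18	0.25	0.96	0.64	0.63	0.91	Group1	3
Subject 5	0.45	0.38	0.95	0.60	0.98	0.93	Group2	4
Subject 6	0.73	0.57	0.93	0.55	0.70	0.94	Group1	4
Subject 7	0.92	0.86	0.93	0.51	0.76	0.94	Group2	4
Subject 8	0.87	0.89	0.93	0.51	0.73	0.93	Group2	4
Subject 9	0.83	0.88	0.96	0.52	0.73	0.94	Group2	4
Subject 10	0.80	0.88	0.97	0.52	0.69	0.93	Group2	3
Subject 11	0.85	0.87	0.98	0.65	0.69	0.94	Group2	4
Subject 12	0.89	0.88	0.96	0.78	0.71	0.95	Group1	4
Subject 13	0.92	0.91	0.95	0.91	0.71	0.96	Group1	4
Subject 14	0.89	0.92	0.95	0.78	0.74	0.92	Group1	3
Subject 15	0.75	0.87	0.90	0.65	0.75	0.87	Group1	3
Subject 16	0.73	0.86	0.91	0.53	0.78	0.83	Group2	4
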