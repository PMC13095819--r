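patient	period	min_q25	min_med	min_q75	min_var	avg_q25	avg_med	avg_q75	avg_var	max_q25	max_med	max_q75	max_var
01-01	m-1	2	2	2	NA	5	6	7	NA	8	8	9	NA
01-01	w1	2	2	2	0	4	5	5	-16.66	8	8	9	0
01-01	w2	2	2	2	0	4	4	5	-33.33	7	8	8	0
01-01	w3	2	2	2	0	4,5	5	5	-16.66	7	8	8	0
01-01	w4	2	2	2	0	5	6	6	0	7	8	8.5	0
01-01	w12-w23	2	2	2	0	4.75	5	6.25	-16.66	8	9	9.25	12.5
01-02	m-1	2	3	4	NA	6	7	7	NA	8	8.5	9	NA
01-02	w1	3	3	4	0	4.5	5	6	-28.57	6,5	7	8	-17.64
01-02	w2	2,5	3	4.5	0	3.5	5	6	-28.57	6	7	7,5	-17.64
01-02	w3	3,5	4	4	33.33	4.5	5	6	-28.57	7	7	8	-17.64
01-02	w4	3,5	4	5	33.33	5.5	6	6	-14.28	7	7	7.5	-17.64
01-02	w12-w23	1	1	1	-66.66	4	5	5	-28.57	6	7	7	-17.64
01-04	m-1	0	0	0	NA	2	2	3	NA	4	8	8	NA
01-04	w1	0	0	0	NA	2	2	2	0	6	6	8	-25
01-04	w2	0	0	0	NA	2	2	2	0	6	6	7	-25
01-04	w3	0	0	0	NA	2	2	2	0	6	6	7	-25
01-04	w4	0	0	0	NA	2	2	2	0	6	8	8	0
01-04	w12-w23	0	0	0	NA	4	4.5	5	125	8	8	9	0
01-05	m-1	4	4	5	NA	6	7	7	NA	9	9	9	NA
01-05	w1	4	4	4	0	6	6	6	-14.28	9	9	9	0
01-05	w2	3	3	4	-25	6	6	6	-14.28	8,5	9	9	0
01-05	w3	3	3	3	-25	6	6	6	-14.28	8	8	8	-11.11
01-05	w4	3	3	3	-25	6	6	6	-14.28	7.5	8	8	-11.11
01-05	w12-w23	2	3	3	-25	5	5	6	-28.57	7.5	8	8	-11.11
01-06	m-1	0	0	0	NA	2	3	3	NA	6	7	7.25	NA
01-06	w1	0	1	1	NA	1.5	2	2.5	-33.33	5	6	6.5	-14.28
01-06	w2	0	0	0,75	NA	2.25	3	3	0	6	6.5	7	-7.14
01-06	w3	0	0	0	NA	1	2	2	-33.33	3,5	4	6.5	-42.85
01-06	w4	0	0	0	NA	2	2	2.5	-33.33	5	5	5.5	-28.57
01-06	w12-w23	0	0	1	NA	3	3	3	0	6.75	7	7	0
All	m-1	0	2	4	NA	3	5	7	NA	7	8	9	NA
All	w1	0	2	3,5	0	2	4	6	-20	6	8	9	0
All	w2	0	2	3	0	3	4	6	-20	6	7	8	-12.5
All	w3	0	2	3	0	2	5	6	0	6	7	8	-12.5
All	w4	0	2	3	0	2	5	6	0	6	7	8	-12.5
All	w12-w23	0	1	2	-50	4	5	5	0	7	8	8.75	0
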