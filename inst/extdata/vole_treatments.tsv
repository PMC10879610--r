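study	experiment_id	condition	treatment	treatment_id	n_voles	diet	contact
Study 1	Experiment 1	Lab	DSR1	E1_F1	1	Grass	No
Study 1	Experiment 1	Lab	DSR2	E1_F2	1	Grass	No
Study 1	Experiment 1	Lab	DSR3	E1_F3	1	Grass	No
Study 1	Experiment 1	Lab	DSR4	E1_F4	1	Grass	No
Study 1	Experiment 1	Lab	DSR5	E1_F5	1	Grass	No
Study 1	Experiment 1	Lab	DSR6	E1_F6	1	Grass	No
Study 1	Experiment 1	Lab	DSR7	E1_F7	1	Grass	No
Study 1	Experiment 1	Lab	DSR8	E1_F8	1	Grass	No
Study 2	Experiment 2	Lab	HC without physical contact	E2_H	9	Chow	No
Study 2	Experiment 2	Lab	LC without physical contact	E2_L	2	Chow	No
Study 2	Experiment 2	Lab	MC without physical contact	E2_M	4	Chow	No
Study 2	Experiment 3	Lab	HD with physical contact	E3_H	8	Chow	Yes
Study 2	Experiment 3	Lab	LD with physical contact	E3_L	2	Chow	Yes
Study 2	Experiment 3	Lab	MD with physical contact	E3_M	4	Chow	Yes
Study 3	Experiment 4	Lab	HD with physical contact	E4_H	8	Chow	Yes
Study 3	Experiment 4	Lab	LD with physical contact	E4_L	2	Chow	Yes
Study 3	Experiment 4	Lab	MD with physical contact	E4_M	4	Chow	Yes
Study 3	Experiment 5	Lab	HD without physical contact	E5_H	8	Chow	No
Study 3	Experiment 5	Lab	MD without physical contact	E5_M	4	Chow	No
Study 3	Experiment 6	Lab	HD with physical contact	E6_H	8	Chow	Yes
Study 3	Experiment 6	Lab	LD with physical contact	E6_L	2	Chow	Yes
Study 3	Experiment 6	Lab	MD with physical contact	E6_M	4	Chow	Yes
Study 3	Experiment 7	Lab	HC without physical contact	E7_H	8	Chow	No
Study 3	Experiment 7	Lab	LC without physical contact	E7_L	2	Chow	No
Study 3	Experiment 7	Lab	MC without physical contact	E7_M	4	Chow	No
Study 3	Experiment 8	Enclosure	HD in enclosures	E8_H1	48	Grass	Yes
Study 3	Experiment 8	Enclosure	LD in enclosures	E8_L1	48	Grass	Yes
Study 3	Experiment 8	Enclosure	MD in enclosures	E8_M1	48	Grass	Yes
Study 3	Experiment 8	Enclosure	HD in enclosures	E8_H2	48	Grass	Yes
Study 3	Experiment 8	Enclosure	LD in enclosures	E8_L2	12	Grass	Yes
Study 3	Experiment 8	Enclosure	MD in enclosures	E8_M2	12	Grass	Yes
Study 3	Experiment 8	Enclosure	HD in enclosures	E8_H3	12	Grass	Yes
Study 3	Experiment 8	Enclosure	LD in enclosures	E8_L3	12	Grass	Yes
Study 3	Experiment 8	Enclosure	MD in enclosures	E8_M3	24	Grass	Yes
Study 3	Experiment 8	Enclosure	HD in enclosures	E8_H4	24	Grass	Yes
Study 3	Experiment 8	Enclosure	LD in enclosures	E8_L4	24	Grass	Yes
Study 3	Experiment 8	Enclosure	MD in enclosures	E8_M4	24	Grass	Yes
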