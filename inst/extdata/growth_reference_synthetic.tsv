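measure	sex	age_lo	age_hi	mean_cm	sd_cm
height	sex-averaged	0	0.99	74.0	2.8
height	sex-averaged	1	1.99	86.0	3.2
height	sex-averaged	2	3.99	98.0	4.0
height	sex-averaged	4	5.99	111.0	4.8
height	sex-averaged	6	7.99	122.0	5.4
height	sex-averaged	8	9.99	133.0	5.9
height	sex-averaged	10	11.99	143.0	6.4
height	sex-averaged	12	13.99	155.0	7.4
height	sex-averaged	14	15.99	166.0	7.6
height	sex-averaged	16	17.99	172.0	7.0
height	sex-averaged	18	40	174.0	6.8
ofc	sex-averaged	0	0.99	46.0	1.4
ofc	sex-averaged	1	1.99	48.2	1.4
ofc	sex-averaged	2	3.99	49.8	1.4
ofc	sex-averaged	4	5.99	51.0	1.4
ofc	sex-averaged	6	7.99	52.2	1.4
ofc	sex-averaged	8	9.99	53.0	1.5
ofc	sex-averaged	10	11.99	53.8	1.5
ofc	sex-averaged	12	13.99	54.6	1.5
ofc	sex-averaged	14	15.99	55.4	1.5
ofc	sex-averaged	16	40	55.8	1.5
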