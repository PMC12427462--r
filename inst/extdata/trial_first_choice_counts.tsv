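pair	scope	count_a	count_b	n_cats	n_days
CDxT150	day1	9	11	20	1
CDxT150	day2	12	8	20	1
CDxT150	overall	21	19	20	2
CDxT300	day1	8	12	20	1
CDxT300	day2	14	5	20	1
CDxT300	overall	22	17	20	2
T150xT300	day1	9	10	20	1
T150xT300	day2	13	6	20	1
T150xT300	overall	22	16	20	2
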