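mouse_id	hour	band	power
m01	1	gamma_40_100	85.05
m01	1	low_2_6	152.9
m01	1	swa_0p5_4	241.2
m01	2	gamma_40_100	27.49
m01	2	low_2_6	130.82
m01	2	swa_0p5_4	185.29
m01	3	gamma_40_100	34.34
m01	3	low_2_6	119.36
m01	3	swa_0p5_4	113.56
m01	4	gamma_40_100	5.74
m01	4	low_2_6	67.39
m01	4	swa_0p5_4	53.81
m01	5	gamma_40_100	55.82
m01	5	low_2_6	89.78
m01	5	swa_0p5_4	101.2
m01	6	gamma_40_100	7.85
m01	6	low_2_6	112.95
m01	6	swa_0p5_4	1
m01	7	gamma_40_100	59.09
m01	7	low_2_6	179.63
m01	7	swa_0p5_4	1
m01	8	gamma_40_100	78.1
m01	8	low_2_6	122.63
m01	8	swa_0p5_4	122.64
m01	9	gamma_40_100	47.33
m01	9	low_2_6	218.9
m01	9	swa_0p5_4	1
m02	1	gamma_40_100	71.21
m02	1	low_2_6	85.03
m02	1	swa_0p5_4	231.27
m02	2	gamma_40_100	58.59
m02	2	low_2_6	61.21
m02	2	swa_0p5_4	181.2
m02	3	gamma_40_100	53.33
m02	3	low_2_6	93.77
m02	3	swa_0p5_4	233.79
m02	4	gamma_40_100	82.4
m02	4	low_2_6	164.45
m02	4	swa_0p5_4	176.33
m02	5	gamma_40_100	82.89
m02	5	low_2_6	132.44
m02	5	swa_0p5_4	45.78
m02	6	gamma_40_100	58.21
m02	6	low_2_6	75.12
m02	6	swa_0p5_4	163.21
m02	7	gamma_40_100	75.94
m02	7	low_2_6	93.91
m02	7	swa_0p5_4	38.82
m02	8	gamma_40_100	47.15
m02	8	low_2_6	123.33
m02	8	swa_0p5_4	1
m02	9	gamma_40_100	3.65
m02	9	low_2_6	34.56
m02	9	swa_0p5_4	1
m03	1	gamma_40_100	63.79
m03	1	low_2_6	110.91
m03	1	swa_0p5_4	166.57
m03	2	gamma_40_100	38.77
m03	2	low_2_6	89.94
m03	2	swa_0p5_4	157.26
m03	3	gamma_40_100	29.77
m03	3	low_2_6	45.16
m03	3	swa_0p5_4	184.26
m03	4	gamma_40_100	64.6
m03	4	low_2_6	14.89
m03	4	swa_0p5_4	119.45
m03	5	gamma_40_100	6.16
m03	5	low_2_6	29.29
m03	5	swa_0p5_4	67.96
m03	6	gamma_40_100	73.79
m03	6	low_2_6	106.83
m03	6	swa_0p5_4	133
m03	7	gamma_40_100	22.85
m03	7	low_2_6	36.31
m03	7	swa_0p5_4	63.42
m03	8	gamma_40_100	66.15
m03	8	low_2_6	103.41
m03	8	swa_0p5_4	72.7
m03	9	gamma_40_100	28.56
m03	9	low_2_6	222.8
m03	9	swa_0p5_4	151.8
m04	1	gamma_40_100	54.41
m04	1	low_2_6	130.16
m04	1	swa_0p5_4	1
m04	2	gamma_40_100	63.13
m04	2	low_2_6	44.79
m04	2	swa_0p5_4	157.95
m04	3	gamma_40_100	44.5
m04	3	low_2_6	253.36
m04	3	swa_0p5_4	61.12
m04	4	gamma_40_100	72.9
m04	4	low_2_6	117.23
m04	4	swa_0p5_4	129.45
m04	5	gamma_40_100	111.06
m04	5	low_2_6	187.13
m04	5	swa_0p5_4	17.07
m04	6	gamma_40_100	58.02
m04	6	low_2_6	134.75
m04	6	swa_0p5_4	24.04
m04	7	gamma_40_100	59.05
m04	7	low_2_6	180.78
m04	7	swa_0p5_4	28.74
m04	8	gamma_40_100	72.4
m04	8	low_2_6	194.39
m04	8	swa_0p5_4	123.59
m04	9	gamma_40_100	67.83
m04	9	low_2_6	56.1
m04	9	swa_0p5_4	214.43
m05	1	gamma_40_100	24.04
m05	1	low_2_6	83.44
m05	1	swa_0p5_4	47.66
m05	2	gamma_40_100	64.66
m05	2	low_2_6	1
m05	2	swa_0p5_4	13.87
m05	3	gamma_40_100	15.77
m05	3	low_2_6	52.46
m05	3	swa_0p5_4	101.65
m05	4	gamma_40_100	109.8
m05	4	low_2_6	179.05
m05	4	swa_0p5_4	1
m05	5	gamma_40_100	42.69
m05	5	low_2_6	111.13
m05	5	swa_0p5_4	107.14
m05	6	gamma_40_100	47.08
m05	6	low_2_6	312.54
m05	6	swa_0p5_4	108.6
m05	7	gamma_40_100	57.6
m05	7	low_2_6	82.22
m05	7	swa_0p5_4	138.95
m05	8	gamma_40_100	111.22
m05	8	low_2_6	150.39
m05	8	swa_0p5_4	183.38
m05	9	gamma_40_100	73.81
m05	9	low_2_6	160.43
m05	9	swa_0p5_4	20.94
m06	1	gamma_40_100	65.48
m06	1	low_2_6	101.53
m06	1	swa_0p5_4	57.23
m06	2	gamma_40_100	54.36
m06	2	low_2_6	172.55
m06	2	swa_0p5_4	2.1
m06	3	gamma_40_100	30.17
m06	3	low_2_6	186.1
m06	3	swa_0p5_4	139.67
m06	4	gamma_40_100	2.55
m06	4	low_2_6	209.92
m06	4	swa_0p5_4	95.15
m06	5	gamma_40_100	62.75
m06	5	low_2_6	185.84
m06	5	swa_0p5_4	156.82
m06	6	gamma_40_100	106.2
m06	6	low_2_6	79.58
m06	6	swa_0p5_4	106.41
m06	7	gamma_40_100	54.35
m06	7	low_2_6	123.62
m06	7	swa_0p5_4	190.11
m06	8	gamma_40_100	56.49
m06	8	low_2_6	127.73
m06	8	swa_0p5_4	159.79
m06	9	gamma_40_100	64.74
m06	9	low_2_6	129.36
m06	9	swa_0p5_4	125.31
m07	1	gamma_40_100	88
m07	1	low_2_6	69.22
m07	1	swa_0p5_4	22.52
m07	2	gamma_40_100	68.44
m07	2	low_2_6	70.77
m07	2	swa_0p5_4	1
m07	3	gamma_40_100	46.38
m07	3	low_2_6	122.93
m07	3	swa_0p5_4	153.88
m07	4	gamma_40_100	67.74
m07	4	low_2_6	78.49
m07	4	swa_0p5_4	194.35
m07	5	gamma_40_100	13.76
m07	5	low_2_6	167.99
m07	5	swa_0p5_4	149.92
m07	6	gamma_40_100	57.95
m07	6	low_2_6	120.18
m07	6	swa_0p5_4	162.29
m07	7	gamma_40_100	57.25
m07	7	low_2_6	68.27
m07	7	swa_0p5_4	137.79
m07	8	gamma_40_100	25.86
m07	8	low_2_6	325.6
m07	8	swa_0p5_4	28.5
m07	9	gamma_40_100	107.14
m07	9	low_2_6	65.64
m07	9	swa_0p5_4	63.06
m08	1	gamma_40_100	45.82
m08	1	low_2_6	87.94
m08	1	swa_0p5_4	1
m08	2	gamma_40_100	90.39
m08	2	low_2_6	100.84
m08	2	swa_0p5_4	106.74
m08	3	gamma_40_100	96.73
m08	3	low_2_6	193.44
m08	3	swa_0p5_4	66.35
m08	4	gamma_40_100	3.69
m08	4	low_2_6	108.52
m08	4	swa_0p5_4	94.09
m08	5	gamma_40_100	1
m08	5	low_2_6	222.02
m08	5	swa_0p5_4	32.45
m08	6	gamma_40_100	7.45
m08	6	low_2_6	176.5
m08	6	swa_0p5_4	44.32
m08	7	gamma_40_100	78.09
m08	7	low_2_6	73.36
m08	7	swa_0p5_4	6.07
m08	8	gamma_40_100	35.09
m08	8	low_2_6	206.15
m08	8	swa_0p5_4	77.64
m08	9	gamma_40_100	104.74
m08	9	low_2_6	156.97
m08	9	swa_0p5_4	1
m09	1	gamma_40_100	70.93
m09	1	low_2_6	51.53
m09	1	swa_0p5_4	37.73
m09	2	gamma_40_100	10.03
m09	2	low_2_6	89.33
m09	2	swa_0p5_4	70.11
m09	3	gamma_40_100	44.26
m09	3	low_2_6	95.09
m09	3	swa_0p5_4	115.16
m09	4	gamma_40_100	80.27
m09	4	low_2_6	108.97
m09	4	swa_0p5_4	208.74
m09	5	gamma_40_100	54.96
m09	5	low_2_6	242.29
m09	5	swa_0p5_4	1
m09	6	gamma_40_100	62.22
m09	6	low_2_6	22.97
m09	6	swa_0p5_4	112.2
m09	7	gamma_40_100	22.62
m09	7	low_2_6	106.74
m09	7	swa_0p5_4	27.3
m09	8	gamma_40_100	15.94
m09	8	low_2_6	127.46
m09	8	swa_0p5_4	103.61
m09	9	gamma_40_100	84.4
m09	9	low_2_6	159.81
m09	9	swa_0p5_4	100.83
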