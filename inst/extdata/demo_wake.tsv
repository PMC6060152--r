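mouse_id	bin_index	wake_fraction
m01	0	1
m01	1	1
m01	2	1
m01	3	1
m01	4	1
m01	5	0.5899
m01	6	0.3843
m01	7	0.381
m01	8	0.4472
m01	9	2e-4
m01	10	0
m01	11	0.0027
m01	12	4e-4
m01	13	0.1886
m01	14	0.1707
m01	15	0.2642
m01	16	0.116
m01	17	0.2458
m01	18	0.1928
m01	19	0.2208
m01	20	0.3312
m01	21	0.0398
m01	22	0.0347
m01	23	0.0388
m01	24	0.0488
m01	25	0.1816
m01	26	0.1318
m01	27	0.0289
m01	28	0.2608
m01	29	1
m01	30	1
m01	31	1
m01	32	1
m01	33	1
m01	34	1
m01	35	1
m01	36	1
m01	37	1
m01	38	1
m01	39	1
m01	40	1
m02	0	1
m02	1	1
m02	2	1
m02	3	1
m02	4	1
m02	5	0.036
m02	6	0.0278
m02	7	0.0155
m02	8	0.0438
m02	9	0.1326
m02	10	0.2321
m02	11	0.3006
m02	12	0.1578
m02	13	0.1828
m02	14	0.107
m02	15	0.1158
m02	16	0.0661
m02	17	0.1297
m02	18	0.2935
m02	19	0.1025
m02	20	0.2533
m02	21	0.08
m02	22	0.0237
m02	23	0.0037
m02	24	0.0396
m02	25	0.0642
m02	26	0.0104
m02	27	0.0312
m02	28	0.029
m02	29	1
m02	30	1
m02	31	1
m02	32	1
m02	33	1
m02	34	1
m02	35	1
m02	36	1
m02	37	1
m02	38	1
m02	39	1
m02	40	1
m03	0	1
m03	1	1
m03	2	1
m03	3	1
m03	4	1
m03	5	0.0072
m03	6	0.0342
m03	7	0.0129
m03	8	0.0322
m03	9	0.1548
m03	10	0.1885
m03	11	0.2312
m03	12	0.2023
m03	13	0.0513
m03	14	0.0111
m03	15	0.172
m03	16	0.0141
m03	17	0.0342
m03	18	0.0429
m03	19	0.0405
m03	20	0.0091
m03	21	0.048
m03	22	0.0391
m03	23	0.0597
m03	24	0.0825
m03	25	0
m03	26	0.001
m03	27	0
m03	28	0
m03	29	1
m03	30	1
m03	31	1
m03	32	1
m03	33	1
m03	34	1
m03	35	1
m03	36	1
m03	37	1
m03	38	1
m03	39	1
m03	40	1
m04	0	1
m04	1	1
m04	2	1
m04	3	1
m04	4	1
m04	5	0.9522
m04	6	0.9941
m04	7	0.9721
m04	8	0.9802
m04	9	1
m04	10	1
m04	11	1
m04	12	1
m04	13	1
m04	14	1
m04	15	1
m04	16	1
m04	17	0.9467
m04	18	0.9889
m04	19	0.9652
m04	20	0.9011
m04	21	0.949
m04	22	0.9567
m04	23	0.9596
m04	24	0.9976
m04	25	0.9923
m04	26	0.9855
m04	27	0.9937
m04	28	0.9959
m04	29	0.2312
m04	30	0.1244
m04	31	0.2077
m04	32	0.2163
m04	33	0.8218
m04	34	0.6956
m04	35	0.89
m04	36	0.7661
m04	37	0.1576
m04	38	0.0733
m04	39	0.1129
m04	40	0.1041
m05	0	1
m05	1	1
m05	2	1
m05	3	1
m05	4	1
m05	5	0.995
m05	6	0.9982
m05	7	0.9962
m05	8	1
m05	9	0.6944
m05	10	0.7995
m05	11	0.7119
m05	12	0.7149
m05	13	0.9173
m05	14	0.7687
m05	15	0.9004
m05	16	0.8459
m05	17	0.9771
m05	18	0.9246
m05	19	0.9881
m05	20	0.9924
m05	21	1
m05	22	1
m05	23	1
m05	24	1
m05	25	0.9852
m05	26	0.9873
m05	27	0.9321
m05	28	0.9187
m05	29	0.1781
m05	30	0.2627
m05	31	0.1301
m05	32	0.1091
m05	33	0.0573
m05	34	0.1052
m05	35	0.1204
m05	36	0.0982
m05	37	0.0532
m05	38	0.1083
m05	39	0.0601
m05	40	0.1092
m06	0	1
m06	1	1
m06	2	1
m06	3	1
m06	4	1
m06	5	0.9762
m06	6	0.9998
m06	7	0.9887
m06	8	1
m06	9	0.9899
m06	10	0.9652
m06	11	0.9159
m06	12	0.9195
m06	13	0.9845
m06	14	0.9761
m06	15	0.9561
m06	16	0.8689
m06	17	0.9982
m06	18	0.9981
m06	19	0.9854
m06	20	0.986
m06	21	0.9999
m06	22	0.9853
m06	23	0.9999
m06	24	0.9999
m06	25	0.9855
m06	26	0.9085
m06	27	0.9723
m06	28	0.9014
m06	29	0.0347
m06	30	0.0227
m06	31	0.0236
m06	32	0.03
m06	33	0.5143
m06	34	0.4617
m06	35	0.4371
m06	36	0.462
m06	37	0.06
m06	38	0.0999
m06	39	0.0721
m06	40	0.151
m07	0	1
m07	1	1
m07	2	1
m07	3	1
m07	4	1
m07	5	0.7395
m07	6	0.536
m07	7	0.6874
m07	8	0.827
m07	9	0.7681
m07	10	0.6497
m07	11	0.683
m07	12	0.7164
m07	13	0.9952
m07	14	0.9973
m07	15	0.9982
m07	16	0.9978
m07	17	0.9411
m07	18	0.8959
m07	19	0.9779
m07	20	0.9887
m07	21	0.9948
m07	22	0.9593
m07	23	0.9215
m07	24	0.9551
m07	25	0.9549
m07	26	0.9801
m07	27	0.9443
m07	28	0.9638
m07	29	1
m07	30	1
m07	31	1
m07	32	1
m07	33	1
m07	34	1
m07	35	1
m07	36	1
m07	37	1
m07	38	1
m07	39	1
m07	40	1
m08	0	1
m08	1	1
m08	2	1
m08	3	1
m08	4	1
m08	5	0.7351
m08	6	0.9072
m08	7	0.7438
m08	8	0.7475
m08	9	0.7184
m08	10	0.873
m08	11	0.8354
m08	12	0.9398
m08	13	0.7732
m08	14	0.7952
m08	15	0.7532
m08	16	0.7234
m08	17	0.7523
m08	18	0.8478
m08	19	0.6261
m08	20	0.7107
m08	21	0.8736
m08	22	0.8772
m08	23	0.961
m08	24	0.9653
m08	25	0.9077
m08	26	0.987
m08	27	0.9791
m08	28	0.9864
m08	29	1
m08	30	1
m08	31	1
m08	32	1
m08	33	1
m08	34	1
m08	35	1
m08	36	1
m08	37	1
m08	38	1
m08	39	1
m08	40	1
m09	0	1
m09	1	1
m09	2	1
m09	3	1
m09	4	1
m09	5	0.9935
m09	6	0.9313
m09	7	0.9564
m09	8	0.9666
m09	9	0.7608
m09	10	0.8382
m09	11	0.7941
m09	12	0.8442
m09	13	0.8668
m09	14	0.9555
m09	15	0.8966
m09	16	0.9191
m09	17	0.4811
m09	18	0.4253
m09	19	0.5525
m09	20	0.4541
m09	21	0.7719
m09	22	0.8374
m09	23	0.8495
m09	24	0.7121
m09	25	0.79990000000000006
m09	26	0.8034
m09	27	0.861
m09	28	0.7692
m09	29	1
m09	30	1
m09	31	1
m09	32	1
m09	33	1
m09	34	1
m09	35	1
m09	36	1
m09	37	1
m09	38	1
m09	39	1
m09	40	1
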