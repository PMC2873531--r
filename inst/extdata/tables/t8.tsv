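test	task	rmse
6	T1	22.9156
6	T2	29.7953
6	T3	24.4563
6	T4	20.2755
6	T5	13.6265
6	T6	25.5433
6	T7	28.6792
6	T8	28.6911
6	T9	13.8089
6	T10	47.9704
6	T11	43.6353
6	T12	13.9306
6	T13	14.4649
6	T14	5.6649
6	T15	35.8113
6	T16	33.6464
6	T17	29.6981
6	T18	29.4559
6	T19	30.2422
6	T20	21.0494
7	T1	22.0309
7	T2	28.8772
7	T3	34.4272
7	T4	22.4800
7	T5	29.5645
7	T6	22.3986
7	T7	23.4719
7	T8	42.3385
7	T9	16.1072
7	T10	34.2505
7	T11	35.4975
7	T12	16.8432
7	T13	13.0795
7	T14	25.0440
7	T15	26.3289
7	T16	36.5158
7	T17	29.9756
7	T18	27.0347
7	T19	26.0495
7	T20	21.7607
8	T1	22.2569
8	T2	29.4852
8	T3	22.9905
8	T4	19.1120
8	T5	11.7851
8	T6	23.5123
8	T7	29.9718
8	T8	28.4760
8	T9	11.7036
8	T10	37.8482
8	T11	41.2163
8	T12	18.2205
8	T13	13.6913
8	T14	5.7872
8	T15	27.3318
8	T16	27.5945
8	T17	23.6955
8	T18	26.5286
8	T19	24.3853
8	T20	16.2990
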