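arm	frac	task	rmse
stl	10	E1	28.3515
stl	30	E1	24.1538
stl	50	E1	23.5544
stl	70	E1	22.8080
stl	90	E1	23.4952
stl	10	E2	28.1353
stl	30	E2	24.7949
stl	50	E2	23.0751
stl	70	E2	21.6717
stl	90	E2	20.5756
stl	10	E3	14.1021
stl	30	E3	12.7868
stl	50	E3	12.8477
stl	70	E3	12.8390
stl	90	E3	11.2925
stl	10	E4	36.7345
stl	30	E4	32.4953
stl	50	E4	30.2501
stl	70	E4	28.5389
stl	90	E4	25.5934
stl	10	E5	37.7847
stl	30	E5	31.7246
stl	50	E5	27.8395
stl	70	E5	27.2221
stl	90	E5	32.1410
stl	10	E6	37.9884
stl	30	E6	36.6409
stl	50	E6	32.8025
stl	70	E6	31.0090
stl	90	E6	27.0574
stl	10	E7	46.1408
stl	30	E7	40.6899
stl	50	E7	32.9677
stl	70	E7	34.0303
stl	90	E7	29.4516
stl	10	E8	29.4008
stl	30	E8	27.4798
stl	50	E8	26.5710
stl	70	E8	24.8380
stl	90	E8	26.7436
stl	10	E9	31.9814
stl	30	E9	15.5796
stl	50	E9	13.6068
stl	70	E9	13.8639
stl	90	E9	12.2373
stl	10	E10	56.8917
stl	30	E10	19.3907
stl	50	E10	13.4394
stl	70	E10	12.8776
stl	90	E10	11.4408
stl	10	E11	40.4318
stl	30	E11	37.2323
stl	50	E11	36.9945
stl	70	E11	34.1775
stl	90	E11	32.1200
stl	10	E12	30.7272
stl	30	E12	29.4070
stl	50	E12	33.6679
stl	70	E12	35.2603
stl	90	E12	24.8004
stl	10	E13	18.8997
stl	30	E13	18.0514
stl	50	E13	17.3333
stl	70	E13	14.1208
stl	90	E13	13.5105
stl	10	E14	34.8579
stl	30	E14	33.0815
stl	50	E14	28.7044
stl	70	E14	25.9012
stl	90	E14	25.7859
mtl	10	E1	27.6417
mtl	30	E1	24.0150
mtl	50	E1	23.5313
mtl	70	E1	22.7155
mtl	90	E1	23.4194
mtl	10	E2	25.4531
mtl	30	E2	22.0457
mtl	50	E2	21.1488
mtl	70	E2	20.6969
mtl	90	E2	20.5423
mtl	10	E3	12.4403
mtl	30	E3	11.5239
mtl	50	E3	11.2708
mtl	70	E3	11.0255
mtl	90	E3	10.0032
mtl	10	E4	31.6222
mtl	30	E4	27.8789
mtl	50	E4	27.9831
mtl	70	E4	27.5373
mtl	90	E4	27.2947
mtl	10	E5	37.6029
mtl	30	E5	27.5771
mtl	50	E5	24.0499
mtl	70	E5	23.5798
mtl	90	E5	24.7571
mtl	10	E6	34.9948
mtl	30	E6	31.9597
mtl	50	E6	30.0650
mtl	70	E6	28.7117
mtl	90	E6	24.6019
mtl	10	E7	45.3279
mtl	30	E7	34.8915
mtl	50	E7	30.3053
mtl	70	E7	29.9185
mtl	90	E7	27.0738
mtl	10	E8	26.5423
mtl	30	E8	24.6162
mtl	50	E8	24.4261
mtl	70	E8	23.7297
mtl	90	E8	24.9686
mtl	10	E9	35.7421
mtl	30	E9	19.8070
mtl	50	E9	17.2665
mtl	70	E9	16.2435
mtl	90	E9	13.3189
mtl	10	E10	56.8917
mtl	30	E10	19.1463
mtl	50	E10	12.9610
mtl	70	E10	12.2792
mtl	90	E10	11.2242
mtl	10	E11	38.9771
mtl	30	E11	31.7360
mtl	50	E11	31.0361
mtl	70	E11	29.2156
mtl	90	E11	28.6740
mtl	10	E12	29.4405
mtl	30	E12	24.4063
mtl	50	E12	24.4616
mtl	70	E12	24.8690
mtl	90	E12	22.1497
mtl	10	E13	18.8997
mtl	30	E13	17.5524
mtl	50	E13	16.4534
mtl	70	E13	13.1908
mtl	90	E13	10.9338
mtl	10	E14	30.0917
mtl	30	E14	27.8195
mtl	50	E14	25.3132
mtl	70	E14	24.3546
mtl	90	E14	24.6832
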