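dataset	arm	subtask	rmse
D1	stl	1	21.7139
D1	stl	2	31.3104
D1	stl	3	22.0464
D1	stl	4	20.5358
D1	stl	5	31.3807
D1	pooled	1	20.8203
D1	pooled	2	24.7029
D1	pooled	3	21.2602
D1	pooled	4	18.7345
D1	pooled	5	28.9061
D2	stl	1	32.3753
D2	stl	2	28.3268
D2	stl	3	27.7405
D2	stl	4	22.1219
D2	stl	5	33.1770
D2	pooled	1	26.9951
D2	pooled	2	25.7676
D2	pooled	3	25.0711
D2	pooled	4	19.9418
D2	pooled	5	32.4254
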