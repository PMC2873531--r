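test	arm	task	rmse
4	stl	IE1	34.1116
4	stl	IE2	35.8600
4	mtl	IE1	29.7394
4	mtl	IE2	30.5459
5	mtl	IE1	26.6910
5	mtl	IE2	26.1009
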