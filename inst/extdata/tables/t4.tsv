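test	task	rmse
1	E1	23.5500
1	E2	23.0800
1	E3	12.8500
1	E4	30.2500
1	E5	27.8400
1	E6	32.8000
1	E7	32.9700
1	E8	26.5700
1	E9	13.6100
1	E10	13.4400
1	E11	36.9900
1	E12	33.6700
1	E13	17.3300
1	E14	28.7000
2	E1	24.9500
2	E2	29.8900
2	E3	31.2700
2	E4	26.8300
2	E5	32.1900
2	E6	29.5200
2	E7	29.2500
2	E8	27.2600
2	E9	15.8700
2	E10	12.3700
2	E11	26.2400
2	E12	30.3800
2	E13	21.4700
2	E14	25.9700
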