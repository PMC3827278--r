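subgenus	region	taxon	n_genotyped	n_after_qc
Muscadinia	North America	V. rotundifolia	71	68
Vitis	North America	V. acerifolia	18	15
Vitis	North America	V. aestivalis	55	42
Vitis	North America	V. cinerea	98	70
Vitis	North America	V. doaniana	5	NA
Vitis	North America	V. girdiana	4	4
Vitis	North America	V. labrusca	36	23
Vitis	North America	V. monticola	5	4
Vitis	North America	V. mustangensis	7	5
Vitis	North America	V. palmata	13	9
Vitis	North America	V. riparia	113	73
Vitis	North America	V. rupestris	48	36
Vitis	North America	V. vulpina	23	15
Vitis	North America	V. x champinii	15	12
Vitis	Eurasia	V. amurensis	22	13
Vitis	East Asia	V. coignetiae	6	3
Vitis	East Asia	V. piasezkii	9	9
Vitis	Eurasia	V. sylvestris	59	59
Vitis	Eurasia	V. vinifera	570	570
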