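track type=bedGraph
chr1	0	200	50
chr1	200	400	19
chr1	400	600	48
chr1	600	800	27
chr1	800	1000	60
chr1	1000	1200	33
chr1	1200	1400	29
chr1	1400	1600	21
chr1	1600	1800	52
chr1	1800	2000	10
chr1	2000	2200	24
chr1	2200	2400	22
chr1	2400	2600	58
chr1	2600	2800	10
chr1	2800	3000	8
chr1	3000	3200	29
chr1	3200	3400	8
chr1	3400	3600	56
chr1	3600	3800	29
chr1	3800	4000	60
chr1	4000	4200	18
chr1	4200	4400	39
chr1	4400	4600	37
chr1	4600	4800	30
chr1	4800	5000	59
chr1	5000	5200	26
chr1	5200	5400	9
chr1	5400	5600	53
chr1	5600	5800	62
chr1	5800	6000	42
chr1	6000	6200	10
chr1	6200	6400	32
chr1	6400	6600	14
chr1	6600	6800	52
chr1	6800	7000	20
chr1	7000	7200	22
chr1	7200	7400	42
chr1	7400	7600	51
chr1	7600	7800	26
chr1	7800	8000	48
chr1	8000	8200	29
chr1	8200	8400	52
chr1	8400	8600	35
chr1	8600	8800	51
chr1	8800	9000	41
chr1	9000	9200	63
chr1	9200	9400	30
chr1	9400	9600	38
chr1	9600	9800	22
chr1	9800	10000	43
chr1	10000	10200	5
chr1	10200	10400	39
chr1	10400	10600	31
chr1	10600	10800	52
chr1	10800	11000	38
chr1	11000	11200	12
chr1	11200	11400	11
chr1	11400	11600	31
chr1	11600	11800	11
chr1	11800	12000	9
chr1	12000	12200	7
chr1	12200	12400	10
chr1	12400	12600	55
chr1	12600	12800	34
chr1	12800	13000	12
chr1	13000	13200	50
chr1	13200	13400	20
chr1	13400	13600	23
chr1	13600	13800	53
chr1	13800	14000	29
chr1	14000	14200	6
chr1	14200	14400	42
chr1	14400	14600	14
chr1	14600	14800	32
chr1	14800	15000	11
chr1	15000	15200	6
chr1	15200	15400	53
chr1	15400	15600	26
chr1	15600	15800	30
chr1	15800	16000	35
chr1	16000	16200	45
chr1	16200	16400	36
chr1	16400	16600	58
chr1	16600	16800	49
chr1	16800	17000	60
chr1	17000	17200	41
chr1	17200	17400	27
chr1	17400	17600	47
chr1	17600	17800	7
chr1	17800	18000	10
chr1	18000	18200	14
chr1	18200	18400	50
chr1	18400	18600	58
chr1	18600	18800	43
chr1	18800	19000	18
chr1	19000	19200	14
chr1	19200	19400	33
chr1	19400	19600	21
chr1	19600	19800	19
chr1	19800	20000	41
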