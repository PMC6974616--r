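track type=bedGraph
chr1	0	200	45
chr1	200	400	30
chr1	400	600	7
chr1	600	800	36
chr1	800	1000	36
chr1	1000	1200	22
chr1	1200	1400	35
chr1	1400	1600	55
chr1	1600	1800	32
chr1	1800	2000	7
chr1	2000	2200	12
chr1	2200	2400	60
chr1	2400	2600	44
chr1	2600	2800	41
chr1	2800	3000	64
chr1	3000	3200	51
chr1	3200	3400	24
chr1	3400	3600	8
chr1	3600	3800	25
chr1	3800	4000	23
chr1	4000	4200	52
chr1	4200	4400	36
chr1	4400	4600	48
chr1	4600	4800	34
chr1	4800	5000	52
chr1	5000	5200	20
chr1	5200	5400	57
chr1	5400	5600	29
chr1	5600	5800	55
chr1	5800	6000	23
chr1	6000	6200	45
chr1	6200	6400	52
chr1	6400	6600	57
chr1	6600	6800	56
chr1	6800	7000	63
chr1	7000	7200	56
chr1	7200	7400	12
chr1	7400	7600	45
chr1	7600	7800	29
chr1	7800	8000	44
chr1	8000	8200	16
chr1	8200	8400	62
chr1	8400	8600	10
chr1	8600	8800	50
chr1	8800	9000	52
chr1	9000	9200	38
chr1	9200	9400	17
chr1	9400	9600	20
chr1	9600	9800	50
chr1	9800	10000	60
chr1	10000	10200	23
chr1	10200	10400	61
chr1	10400	10600	30
chr1	10600	10800	31
chr1	10800	11000	42
chr1	11000	11200	46
chr1	11200	11400	62
chr1	11400	11600	23
chr1	11600	11800	7
chr1	11800	12000	56
chr1	12000	12200	19
chr1	12200	12400	34
chr1	12400	12600	56
chr1	12600	12800	11
chr1	12800	13000	41
chr1	13000	13200	23
chr1	13200	13400	45
chr1	13400	13600	14
chr1	13600	13800	9
chr1	13800	14000	62
chr1	14000	14200	40
chr1	14200	14400	42
chr1	14400	14600	44
chr1	14600	14800	41
chr1	14800	15000	38
chr1	15000	15200	6
chr1	15200	15400	46
chr1	15400	15600	13
chr1	15600	15800	52
chr1	15800	16000	33
chr1	16000	16200	58
chr1	16200	16400	39
chr1	16400	16600	29
chr1	16600	16800	51
chr1	16800	17000	57
chr1	17000	17200	42
chr1	17200	17400	21
chr1	17400	17600	53
chr1	17600	17800	31
chr1	17800	18000	18
chr1	18000	18200	50
chr1	18200	18400	60
chr1	18400	18600	17
chr1	18600	18800	59
chr1	18800	19000	50
chr1	19000	19200	43
chr1	19200	19400	54
chr1	19400	19600	20
chr1	19600	19800	10
chr1	19800	20000	58
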