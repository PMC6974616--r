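track type=bedGraph
chr1	0	200	44
chr1	200	400	27
chr1	400	600	6
chr1	600	800	37
chr1	800	1000	34
chr1	1000	1200	23
chr1	1200	1400	37
chr1	1400	1600	54
chr1	1600	1800	32
chr1	1800	2000	8
chr1	2000	2200	12
chr1	2200	2400	61
chr1	2400	2600	43
chr1	2600	2800	38
chr1	2800	3000	64
chr1	3000	3200	51
chr1	3200	3400	22
chr1	3400	3600	10
chr1	3600	3800	24
chr1	3800	4000	19
chr1	4000	4200	54
chr1	4200	4400	34
chr1	4400	4600	49
chr1	4600	4800	33
chr1	4800	5000	56
chr1	5000	5200	22
chr1	5200	5400	56
chr1	5400	5600	30
chr1	5600	5800	54
chr1	5800	6000	23
chr1	6000	6200	44
chr1	6200	6400	52
chr1	6400	6600	58
chr1	6600	6800	59
chr1	6800	7000	63
chr1	7000	7200	56
chr1	7200	7400	13
chr1	7400	7600	44
chr1	7600	7800	29
chr1	7800	8000	45
chr1	8000	8200	16
chr1	8200	8400	59
chr1	8400	8600	11
chr1	8600	8800	53
chr1	8800	9000	49
chr1	9000	9200	36
chr1	9200	9400	19
chr1	9400	9600	20
chr1	9600	9800	46
chr1	9800	10000	61
chr1	10000	10200	25
chr1	10200	10400	61
chr1	10400	10600	29
chr1	10600	10800	34
chr1	10800	11000	40
chr1	11000	11200	44
chr1	11200	11400	63
chr1	11400	11600	23
chr1	11600	11800	7
chr1	11800	12000	55
chr1	12000	12200	20
chr1	12200	12400	33
chr1	12400	12600	57
chr1	12600	12800	14
chr1	12800	13000	41
chr1	13000	13200	21
chr1	13200	13400	46
chr1	13400	13600	10
chr1	13600	13800	9
chr1	13800	14000	59
chr1	14000	14200	43
chr1	14200	14400	44
chr1	14400	14600	42
chr1	14600	14800	41
chr1	14800	15000	35
chr1	15000	15200	7
chr1	15200	15400	46
chr1	15400	15600	12
chr1	15600	15800	52
chr1	15800	16000	30
chr1	16000	16200	57
chr1	16200	16400	38
chr1	16400	16600	28
chr1	16600	16800	50
chr1	16800	17000	56
chr1	17000	17200	44
chr1	17200	17400	23
chr1	17400	17600	53
chr1	17600	17800	31
chr1	17800	18000	18
chr1	18000	18200	47
chr1	18200	18400	62
chr1	18400	18600	13
chr1	18600	18800	57
chr1	18800	19000	52
chr1	19000	19200	42
chr1	19200	19400	54
chr1	19400	19600	20
chr1	19600	19800	11
chr1	19800	20000	58
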