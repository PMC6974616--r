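chr1	2500	4000	gene01	0	+
chr1	4500	6000	gene02	0	-
chr1	6500	8000	gene03	0	+
chr1	8500	10000	gene04	0	-
chr1	10500	12000	gene05	0	+
chr1	12500	14000	gene06	0	-
chr1	14500	16000	gene07	0	+
chr1	16500	18000	gene08	0	-
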