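cancer_type	mark	path
T01	markA	T01_markA.bedGraph
T02	markA	T02_markA.bedGraph
T03	markA	T03_markA.bedGraph
T01	markB	T01_markB.bedGraph
T02	markB	T02_markB.bedGraph
T03	markB	T03_markB.bedGraph
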