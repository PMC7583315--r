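rsid	gene	offset	ref	alt
rs1452787381	SHOX	-45	A	G
rs1393008234	GTPBP6	-24	G	T
rs1402972626	ASMT	-30	G	A
rs1452787381	ZFY	-56	C	T
rs20067072	CDY2A	-24	T	C
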