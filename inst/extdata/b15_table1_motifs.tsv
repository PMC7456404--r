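label	aa24	aa45_46	aa63	aa65_67	aa70	epitope	aa77	aa80_83	aa166_167
B62	A	MA	E	QIS/QIF/QIC	N	Bw6	S	NLRG	EW
B62-Bw4	A	MA	E	QIS	N	Bw4	N	IALR	EW
B63	A	MA	E	RNM	S	Bw4	N	IALR	EW
B71	S	EE	N	QIC/QIF/QIS	N	Bw6	S	NLRG	EW
B71-Bw4	S	EE	N	QIC	N	Bw4	N	IALR	EW
B72	S	EE	E	QIS	N	Bw6	S	NLRG	EW
B75	A	MA	N	QIS/QIY/QIC	N	Bw6	S	NLRG	EW
B76	A	MA	E	QIS	N	Bw6	S	NLRG	DG/ES
B77	A	MA	N	QIS	N	Bw4	N	IALR	EW
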