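allele	aa24	aa45	aa46	aa63	aa65	aa66	aa67	aa70	aa77	aa80	aa81	aa82	aa83	aa166	aa167	expected_label	source_table
B*15:08	A	M	A	N	Q	I	F	N	S	N	L	R	G	E	W	B75	T2
B*15:15	A	M	A	N	Q	I	S	N	S	N	L	R	G	E	W	B75	T2
B*15:23	S	E	E	N	Q	I	C	N	N	I	A	L	R	E	W	B71-Bw4	T2
B*15:43	A	M	A	E	Q	I	S	N	D	T	L	L	R	E	W	B62-Bw4	T2
B*15:87	A	M	A	E	Q	I	S	N	S	I	A	L	R	E	W	B62-Bw4	T2
B*15:115	S	E	E	N	Q	I	C	N	S	T	A	L	R	E	W	B71-Bw4	T2
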