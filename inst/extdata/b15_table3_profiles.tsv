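allele	aa24	aa45	aa46	aa63	aa65	aa66	aa67	aa70	aa77	aa80	aa81	aa82	aa83	aa166	aa167	expected_label	source_table
B*15:36	A	M	A	E	Q	I	S	N	N	T	A	L	R	E	W	B62-Bw4	T3
B*15:46	A	K	E	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T3
B*15:52	S	E	E	N	Q	I	C	N	S	N	L	R	G	E	W	B71	T3
B*15:53	T	K	E	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T3
B*15:62	S	E	E	E	Q	I	S	N	S	N	L	R	G	E	W	B72	T3
B*15:68	S	E	E	E	Q	I	S	N	S	N	L	R	G	E	W	B72	T3
B*15:76	A	M	A	N	Q	I	Y	Q	S	N	L	R	G	E	W	UNASSIGNED	T3
B*15:86	A	M	A	E	Q	I	S	N	S	N	L	R	G	E	W	B62	T3
B*15:91	S	E	E	E	Q	I	S	N	S	N	L	R	G	E	S	UNASSIGNED	T3
B*15:101	A	M	A	E	Q	I	Y	Q	S	N	L	R	G	E	S	UNASSIGNED	T3
B*15:106	A	K	E	E	Q	I	S	N	S	N	L	R	G	E	S	UNASSIGNED	T3
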