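allele	aa24	aa45	aa46	aa63	aa65	aa66	aa67	aa70	aa77	aa80	aa81	aa82	aa83	aa166	aa167	expected_label	source_table
B*15:143	A	K	E	N	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:183	T	M	A	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:202	A	T	A	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:212	T	K	E	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:239	A	T	E	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:251	S	M	A	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:259	A	E	E	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:308	A	T	E	N	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:336	T	M	A	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:345	T	M	A	N	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:376	S	T	E	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:392	A	M	A	G	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:429	S	M	A	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:430	A	M	A	E	Q	I	S	N	S	K	L	R	G	E	W	UNASSIGNED	T4
B*15:434	S	G	E	N	Q	I	C	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:436	S	G	E	N	Q	I	C	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:504	A	E	E	N	Q	I	C	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:511	T	E	E	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:525	A	K	E	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:545	S	M	A	E	Q	I	C	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:553	A	E	E	N	Q	I	F	N	S	N	L	R	G	E	W	UNASSIGNED	T4
B*15:556	S	M	A	E	Q	I	S	N	S	N	L	R	G	E	W	UNASSIGNED	T4
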