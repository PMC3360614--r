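pair1_x	pair1_y	pair2_x	pair2_y	dg
A	U	A	U	-0.93
A	U	U	A	-1.10
A	U	C	G	-2.24
A	U	G	C	-2.08
U	A	A	U	-1.33
U	A	U	A	-0.93
U	A	C	G	-2.35
U	A	G	C	-2.11
C	G	A	U	-2.11
C	G	U	A	-2.08
C	G	C	G	-3.26
C	G	G	C	-2.36
G	C	A	U	-2.35
G	C	U	A	-2.24
G	C	C	G	-3.42
G	C	G	C	-3.26
A	U	G	U	-0.55
A	U	U	G	-1.36
U	A	G	U	-1.27
U	A	U	G	-1.00
C	G	G	U	-1.41
C	G	U	G	-2.11
G	C	G	U	-1.53
G	C	U	G	-2.51
G	U	A	U	-1.00
G	U	U	A	-1.36
G	U	C	G	-2.51
G	U	G	C	-2.11
G	U	G	U	-0.50
G	U	U	G	1.29
U	G	A	U	-1.27
U	G	U	A	-0.55
U	G	C	G	-1.53
U	G	G	C	-1.41
U	G	G	U	0.30
U	G	U	G	-0.50
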