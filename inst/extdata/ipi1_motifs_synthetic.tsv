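index	class	aa6	aa1p
1	P	T	D
2	L	N	D
3	S	S	N
4	P	T	N
5	L	N	S
6	S	T	D
7	P	N	D
8	L	S	N
9	S	N	S
10	P	T	D
11	L	T	N
12	S	N	D
13	P	S	N
14	E	A	-
15	DYW	-	-
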