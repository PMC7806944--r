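component	windows	ns_per_window
equilibration	1	80
a	16	6
l	16	6
t	16	6
e	12	2.4
v	12	24
w	12	12
f	12	2.4
c	16	12
r	16	12
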