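code	term	method	dG	sigma
e	elec_bound	MBAR	-8.7	0.3
e	elec_bound	TI-GQ	-8.3	0.5
v	LJ_bound	MBAR	10.1	0.2
v	LJ_bound	TI-GQ	10.0	0.2
w	LJ_unbound	MBAR	-0.9	0.1
w	LJ_unbound	TI-GQ	-1.0	0.1
f	elec_unbound	MBAR	-11.1	0.02
f	elec_unbound	TI-GQ	-11.0	0.1
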