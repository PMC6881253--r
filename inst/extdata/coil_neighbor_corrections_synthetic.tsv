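neighbor	side	nucleus	delta_ppm
P	next	CA	-1.90
P	prev	CA	-0.20
V	next	CA	-0.10
I	next	CA	-0.10
T	next	CA	-0.10
G	next	CA	0.08
G	prev	CA	0.08
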