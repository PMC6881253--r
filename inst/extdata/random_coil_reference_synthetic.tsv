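residue	nucleus	shift_ppm
A	CA	52.8
R	CA	56.5
N	CA	53.3
D	CA	54.4
C	CA	58.3
Q	CA	56.2
E	CA	56.7
G	CA	45.3
H	CA	55.5
I	CA	61.6
L	CA	55.5
K	CA	56.7
M	CA	55.8
F	CA	58.1
P	CA	63.5
S	CA	58.7
T	CA	62.0
W	CA	57.6
Y	CA	58.0
V	CA	62.6
A	C	177.6
R	C	176.6
N	C	175.5
D	C	176.5
C	C	174.8
Q	C	176.3
E	C	176.8
G	C	174.2
H	C	175.1
I	C	176.5
L	C	177.5
K	C	176.8
M	C	176.7
F	C	176.0
P	C	177.1
S	C	174.9
T	C	174.8
W	C	176.5
Y	C	175.9
V	C	176.5
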