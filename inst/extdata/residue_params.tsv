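residue	class	ss_min_dist	bb_slots	ss_slots	charge
A	generic	0.54	2	2	0
C	generic	0.60	2	2	0
D	generic	0.62	2	3	-1
E	generic	0.68	2	3	-1
F	generic	0.74	2	4	0
G	glycine	0.50	2	1	0
H	generic	0.70	2	3	0
I	generic	0.68	2	3	0
K	generic	0.74	2	4	1
L	generic	0.70	2	3	0
M	generic	0.70	2	3	0
N	generic	0.64	2	3	0
P	proline	0.62	2	2	0
Q	generic	0.68	2	3	0
R	generic	0.78	2	4	1
S	generic	0.56	2	2	0
T	generic	0.60	2	2	0
V	generic	0.64	2	3	0
W	generic	0.80	2	4	0
Y	generic	0.76	2	4	0
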