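# Amino-acid compressibility magnitudes |K0| (m^3 mol^-1 Pa^-1 x 1e-15).
# SYNTHETIC reconstruction: the published per-residue scale was not
# redistributable, so this table anchors the six pairwise differences that
# the rhodopsin convergence analysis constrains (A-S, P-L, V-I, H-K, L-F,
# S-T) and fills the remaining residues with plausible distinct magnitudes.
# Any 20-value scale can be injected in its place via read_property_scale().
aa	K0
A	1.00
R	9.90
N	4.90
D	4.40
C	3.20
Q	6.60
E	5.90
G	0.50
H	7.60
I	11.20
L	10.50
K	9.10
M	11.80
F	13.25
P	2.10
S	5.30
T	6.46
W	16.00
Y	13.90
V	10.05
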