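# Rigidity-oriented normalized B-value scale: the Vihinen-type values
# reflected about their mean (v' = 2*mean(v) - v), so that larger value =
# more rigid residue and the segment index 1/mBf grows with flexibility,
# matching the orientation of published 1/mBf channel tables.
# Calibrated orientation; raw per-residue values remain auditable here.
residue	value
A	0.9973
C	1.0753
D	0.9133
E	0.8873
F	1.0663
G	0.9503
H	1.0313
I	1.0543
K	0.8793
L	1.0463
M	1.0293
N	0.9333
P	0.9323
Q	0.9443
R	0.9733
S	0.9353
T	0.9843
V	1.0503
W	1.0773
Y	1.0523
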