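# Representative mean relative solvent accessibility (RSA) per residue:
# fraction of the side chain exposed in folded globular proteins, compiled
# for this package as a hydropathy-consistent summary table. Values in [0,1].
residue	value
A	0.405
C	0.268
D	0.651
E	0.673
F	0.290
G	0.588
H	0.485
I	0.273
K	0.710
L	0.290
M	0.324
N	0.621
P	0.502
Q	0.620
R	0.628
S	0.568
T	0.480
V	0.306
W	0.279
Y	0.319
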