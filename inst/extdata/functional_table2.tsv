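# S3 flexibility indices (1/mBf) and stretch-induced shifts of the
# half-activation voltage (delta V1/2, mV) for mechanosensitive members,
# transcribed from the published stretch-activation table. The Cav2 DIII
# activation midpoint shows no stretch shift; the quoted interval is the
# inactivation shift.
channel	domain	s3_index	s3s4_index	charge_e0	mechanosensitive	dv12_shift
Nav1.5	DI	1.61	1.71	~ 12	yes	~ -5 - -35
BK (Slo1)	-	1.55	1.67	2.4 - 4.4	yes	~ -4 - -20
Nav1.5	DIV	1.55	1.64	~ 12	yes	~ -5 - -35
Shaker Kv1	-	1.48	1.96	12 - 16	yes	-8.8 +/- 1.3
Cav1 DI	DI	1.48	1.79	~ 9	yes	-1.4 +/- 0.4
Nav1.5	DIII	1.45	1.73	~ 12	yes	~ -5 - -35
Cav2 DIII	DIII	1.44	1.92	~ 9	yes	-7 - -18
Kv7.1 (KCNQ1)	-	1.41	1.61	~ 8	yes	-13 +/- 1.9
hHv1	-	1.40	1.49	6	yes	-14.4
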