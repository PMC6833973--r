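# Local S3/S3-S4/S1-S4 flexibility indices (1/mBf), voltage dependence
# (charge per channel, elementary charges e0) and temperature coefficients
# (Q10 of the activation and inactivation time constants) for selected ion
# channels, transcribed from the published comparison table.
# "n.d." = not determined; "-" = not reported; "~" = approximate;
# ranges use "a - b"; "x ; y" lists two reported values.
channel	domain	s3_index	s3s4_index	s1s4_index	charge_e0	q10_act	q10_inact
Shaker Kv1	-	1.48	1.96	1.87	12 - 16	~ 4	7.2
Kv1.2	-	1.61	1.86	1.82	10	n.d.	n.d.
Na+-channel (frog muscle)	-	-	-	-	~ 12	2.4	3 - 5.3
Na+-channel (muscle)	-	-	-	-	~ 12	2.3	3.4 - 9.1
Nav1.5	DI	1.56	1.69	1.67	~ 12	1.25	4 ; 5.8
Nav1.5	DIV	1.51	1.62	1.68	~ 12	1.25	4 ; 5.8
Ca2+-channel (muscle)	-	-	-	-	8.6 - 15	~ 3.0	n.d.
Cav1.2	DII	1.58	1.70	1.67	~ 9	n.d.	3
Cav1.2	DIV	1.62	1.90	1.70	~ 9	n.d.	3
Cav1.4	DII	1.66	1.68	1.65	~ 9	n.d.	~ 19
Cav1.4	DIV	1.62	1.97	1.75	~ 9	n.d.	~ 19
Kv7.4 (KCNQ4)	-	1.53	1.62	1.58	~ 8	8.3	n.d.
Kv11.3	-	1.56	1.84	1.81	8	3.8	2.6
Kv11.1 (hERG)	-	1.51	1.80	1.74	6 - 8	4.7	2.9
HCN2	-	1.63	1.73	1.80	5 - 8	n.d.	n.d.
HCN1	-	1.62	1.73	1.78	3.75	2.9	3.1
hHv1	-	1.40	1.49	1.50	6	6 - 9	-
mHv1	-	1.40	1.46	1.49	4	6 - 9	-
BK (Slo1)	-	1.55	1.67	1.64	2.4 - 4.4	n.d.	n.d.
ciVSP	-	1.52	1.63	1.66	~ 1.25	1.4	1.7
mTRPM8	-	1.51	1.59	1.60	0.9	1.2	5.2 - 9.4
mTRPA1	-	1.50	1.45	1.69	n.d.	2.8	-
DmTRPA1	-	1.47	1.54	1.72	n.d.	11	-
TRPV1	-	1.44	1.52	1.66	0.5 - 0.7	~ 15 - 40	1.35
TRPV2	-	1.49	1.52	1.55	n.d.	> 100	-
CNGA1	-	1.77	1.93	1.82	~ 0.22	n.d.	-
CNGA2	-	1.64	1.78	1.68	n.d.	2 - 6	-
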