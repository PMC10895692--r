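# Published worked example: nonadiabatic transition counts among the 10
# MCH states visited by a representative LONG trajectory ending in T1
# (2088 transitions at a 0.5 fs step).
# Rows = from-state, columns = to-state; diagonal = within-state steps.
state	S0	S1	S2	S3	T1,-1	T2,-1	T1,0	T2,0	T1,1	T2,1
S0	51	0	1	0	2	0	5	1	0	0
S1	4	203	4	1	2	1	0	8	1	3
S2	0	4	42	0	1	0	0	1	0	1
S3	0	0	1	24	0	0	0	0	0	0
T1,-1	3	1	0	0	474	3	14	1	16	2
T2,-1	0	4	0	0	3	176	0	8	1	10
T1,0	2	3	0	0	14	0	266	4	16	0
T2,0	0	8	0	0	1	7	4	219	0	9
T1,1	1	0	0	0	16	1	15	1	239	1
T2,1	0	4	1	0	1	14	0	5	1	158
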