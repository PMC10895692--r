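# Published worked example: nonadiabatic transition counts among the 10
# MCH states visited by a representative SHORT trajectory ending in T1
# (159 transitions at a 0.5 fs step, i.e. 79.5 fs to reach 3.7 A).
# Rows = from-state, columns = to-state; diagonal = within-state steps.
state	S0	S1	S2	S3	T1,-1	T2,-1	T1,0	T2,0	T1,1	T2,1
S0	59	0	0	0	1	0	0	0	0	0
S1	1	10	0	0	0	0	0	0	0	0
S2	0	0	0	0	0	0	0	0	0	0
S3	0	0	0	0	0	0	0	0	0	0
T1,-1	1	0	0	0	5	0	0	1	0	0
T2,-1	0	1	0	0	0	0	0	0	0	0
T1,0	0	0	0	0	0	0	0	0	0	0
T2,0	0	0	0	0	0	1	0	1	0	0
T1,1	0	0	0	0	1	0	0	0	60	1
T2,1	0	0	0	0	0	0	0	0	1	15
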