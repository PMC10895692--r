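# Published worked example: O1-O2-C3-C4 dihedral waypoints (degrees) of the
# long T1 trajectory; 180 and -180 are the same dihedral angle.
135.8
180.0
-90.0
0.0
32.9
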