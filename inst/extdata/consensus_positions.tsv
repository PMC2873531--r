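# Position-dependent nucleotide consensus for 19-nt sense strands, compiled
# from published rational siRNA design rules (G/C at the 5' sense end, A/U at
# the 3' sense end, A at positions 3 and 6, U at position 10, no G at 13).
# Positions are 1-based on the sense strand; empty field = no constraint.
# Editable approximation: the consensus feature definitions are not fixed by
# the feature list that names them.
position	preferred	avoided
1	G,C
3	A
6	A
10	U
13		G
19	A,U	G,C
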