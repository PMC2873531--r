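# Dinucleotide sets for the preferred/avoided dinucleotide content indices.
# Weakly pairing (A/U-rich) steps are treated as preferred, strongly pairing
# (G/C-rich) steps as avoided, following the thermodynamic-asymmetry design
# rules. Editable approximation.
set	dinucleotides
preferred	AA,UU,UA,AU
avoided	GC,CG,GG,CC
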