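# RNA/RNA nearest-neighbor stacking free energies, delta-G at 37 C (kcal/mol),
# Freier-style parameter set for Watson-Crick duplex steps. A step "XY" is the
# dinucleotide 5'-XY-3' on the sense strand paired with its complement; values
# obey the reverse-complement symmetry dG(XY) == dG(rc(XY)).
# "init" is the duplex initiation term. Editable; more negative = more stable.
step	dg
AA	-0.9
AC	-2.1
AG	-1.7
AU	-0.9
CA	-1.8
CC	-2.9
CG	-2.0
CU	-1.7
GA	-2.3
GC	-3.4
GG	-2.9
GU	-2.1
UA	-1.1
UC	-2.3
UG	-1.8
UU	-0.9
init	3.4
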