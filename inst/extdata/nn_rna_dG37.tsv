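# RNA/RNA nearest-neighbor stacking free energies, Delta-G37 in kcal/mol
# source: Xia et al. (1998) Biochemistry 37:14719 (Turner lab unified parameters)
# version: 1.0
# step = dinucleotide 5'->3' on the reference strand of a Watson-Crick duplex;
# the paired step on the partner strand is its reverse complement.
# "init" = duplex initiation; "term_AU" = per-end terminal A-U pair penalty.
step	dG37
AA	-0.93
UU	-0.93
AU	-1.10
UA	-1.33
CU	-2.08
AG	-2.08
CA	-2.11
UG	-2.11
GU	-2.24
AC	-2.24
GA	-2.35
UC	-2.35
CG	-2.36
GG	-3.26
CC	-3.26
GC	-3.42
init	4.09
term_AU	0.45
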