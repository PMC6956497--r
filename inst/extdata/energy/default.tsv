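# seedscan energy parameter file
# sections: [meta] [stack] [loop] [init] [terminal]
# stack: dyad 'P1/P2' = pair P1 (5' RNA1 side) followed by pair P2, kcal/mol
# loop: cost a + b*ln(u) for u >= 1 unpaired bases (interior/bulge loops;
#       also hairpin loops of the intramolecular accessibility ensemble)
# terminal: helix-end penalty per closing pair, kcal/mol
[meta]
name	default
temperature	310.15
[stack]
AU/AU	-1.10
AU/UA	-1.10
AU/CG	-2.10
AU/GC	-2.10
AU/GU	-0.80
AU/UG	-0.80
UA/AU	-1.10
UA/UA	-1.10
UA/CG	-2.10
UA/GC	-2.10
UA/GU	-0.80
UA/UG	-0.80
CG/AU	-2.10
CG/UA	-2.10
CG/CG	-3.10
CG/GC	-3.10
CG/GU	-1.80
CG/UG	-1.80
GC/AU	-2.10
GC/UA	-2.10
GC/CG	-3.10
GC/GC	-3.10
GC/GU	-1.80
GC/UG	-1.80
GU/AU	-0.80
GU/UA	-0.80
GU/CG	-1.80
GU/GC	-1.80
GU/GU	-0.50
GU/UG	-0.50
UG/AU	-0.80
UG/UA	-0.80
UG/CG	-1.80
UG/GC	-1.80
UG/GU	-0.50
UG/UG	-0.50
[loop]
a	3.40
b	0.85
[init]
init	4.10
[terminal]
AU	0.45
UA	0.45
GU	0.45
UG	0.45
CG	0.00
GC	0.00
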