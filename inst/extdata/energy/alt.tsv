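# seedscan energy parameter file
# sections: [meta] [stack] [loop] [init] [terminal]
# stack: dyad 'P1/P2' = pair P1 (5' RNA1 side) followed by pair P2, kcal/mol
# loop: cost a + b*ln(u) for u >= 1 unpaired bases (interior/bulge loops;
#       also hairpin loops of the intramolecular accessibility ensemble)
# terminal: helix-end penalty per closing pair, kcal/mol
[meta]
name	alt
temperature	310.15
[stack]
AU/AU	-1.00
AU/UA	-1.00
AU/CG	-2.20
AU/GC	-2.20
AU/GU	-0.68
AU/UG	-0.68
UA/AU	-1.00
UA/UA	-1.00
UA/CG	-2.20
UA/GC	-2.20
UA/GU	-0.68
UA/UG	-0.68
CG/AU	-2.20
CG/UA	-2.20
CG/CG	-3.40
CG/GC	-3.40
CG/GU	-1.88
CG/UG	-1.88
GC/AU	-2.20
GC/UA	-2.20
GC/CG	-3.40
GC/GC	-3.40
GC/GU	-1.88
GC/UG	-1.88
GU/AU	-0.68
GU/UA	-0.68
GU/CG	-1.88
GU/GC	-1.88
GU/GU	-0.35
GU/UG	-0.35
UG/AU	-0.68
UG/UA	-0.68
UG/CG	-1.88
UG/GC	-1.88
UG/GU	-0.35
UG/UG	-0.35
[loop]
a	3.10
b	0.95
[init]
init	4.00
[terminal]
AU	0.50
UA	0.50
GU	0.50
UG	0.50
CG	0.00
GC	0.00
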