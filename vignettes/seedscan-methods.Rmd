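---
title: "Models and methods behind seedscan"
author: "seedscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seedscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscan)
```

## The interaction model

`seedscan` scores an RNA–RNA interaction between an sRNA (RNA1) and a
target window (RNA2) as

$$E \;=\; E_h \;+\; ED^1_{i..j} \;+\; ED^2_{k..l},$$

the sum of the hybridization free energy of the intermolecular duplex
and two accessibility penalties, one per interaction site. A duplex is a
non-crossing set of canonical base pairs (`AU`, `UA`, `CG`, `GC`, `GU`,
`UG`); RNA1 positions ascend 5'→3' while the paired RNA2 positions
descend (antiparallel geometry). `predict_interaction()` returns the
duplex minimizing $E$ subject to the configured constraints, or nothing
when no constraint-satisfying duplex reaches the energy threshold
(`intMaxE`, default 0 kcal/mol: only net-stabilizing interactions are
reported).

### Hybridization energy

$E_h$ follows the nearest-neighbor decomposition: a duplex initiation
term, one stacking term per directly adjacent pair dyad (a 36-entry
table), one interior-loop/bulge term per dyad separated by unpaired
bases, and a helix-end penalty for terminal AU/GU pairs. The loop cost
is the two-parameter form $a + b\,\ln(u_1+u_2)$, logarithmic in the
total number of unpaired bases, as in standard loop-entropy models.

Parameter sets are plain sectioned TSV files (`[meta]`, `[stack]`,
`[loop]`, `[init]`, `[terminal]`); two compact presets ship with the
package (`"default"`, `"alt"`). The shipped tables are intentionally
compact: stack entries derive from per-pair strengths (GC-type dyads
about −3 kcal/mol, AU about −1, GU wobble about −0.5, initiation +4.1),
which preserves the orderings that matter for constraint behaviour —
GC-rich stacks strongest, wobble stacks weakest, GU substitution never
stabilizing — without reproducing any published table. The file format
accepts full 36-entry tables, so externally derived parameters can be
dropped in. The table is symmetric under reading the duplex from the
opposite end, which makes $E_h$ invariant under strand-role reversal (a
tested property). Temperature defaults to 310.15 K; all energies are
kcal/mol. Dangling ends and coaxial stacking are out of model.

### Accessibility

For each RNA the package computes an *accessibility profile*: the exact
probability $P^u(i..j)$ that region $i..j$ is completely unpaired in the
Boltzmann ensemble of intramolecular secondary structures, for every
region up to a maximal length (typically the maximal interaction
length, which bounds the precomputation). The penalty for occupying a
region is $ED = -RT\,\ln P^u$ with $R = 0.0019872$ kcal/(mol·K);
probabilities are floored at $10^{-10}$ so penalties stay finite and
comparisons remain total.

The intramolecular ensemble uses the *same* parameter set as
hybridization: stacked dyads score by the stack table, hairpin loops
cost $a + b\ln u$ (minimum hairpin 3 nt), interior/bulge loops cost
$a + b\ln(u_1+u_2)$ with each side capped at 10 unpaired nt (larger
interior loops are excluded from the ensemble — the customary treatment,
since their Boltzmann weight is negligible and the cap makes the
recursions quadratic), multiloops cost the constant $a$, and exterior
bases are free. This single self-consistent model keeps every energy in
the pipeline on one scale. Two simplifications are deliberate: no
per-branch multiloop terms, and no intramolecular helix-end penalties.

$P^u$ is computed by an inside/outside decomposition. The inside pass
tabulates segment partition functions ($Z$, pair-closed $Z_b$, and the
exactly-one-branch restriction $Q_1$). The outside pass computes, for
every pair $(p,q)$, the partition function of everything outside that
pair. The probability that a region is unpaired then decomposes over the
*innermost* base pair enclosing the region — none (the sequence splits
into independent flanks), a hairpin loop, an interior loop whose single
branch leaves the region in one of its two gaps, or a multiloop whose
branches distribute over the two flanks. Prefix tables collapse the
resulting double sums, so all $O(n \cdot \mathrm{maxlen})$ regions of a
300-nt window are obtained in well under a second. Windows are folded
globally (the whole input sequence is the folding unit); local-window
folding of longer sequences is not implemented — callers control
locality by the window they pass in.

Correctness is established against exhaustive structure enumeration
(`enumerate_structures()`, itself checked against an independent
counting recursion): for sequences up to 12 nt every region probability
matches full Boltzmann enumeration to $10^{-8}$, and subsequence
monotonicity ($P^u$ of a region never exceeds that of any subregion)
holds across all tested instances.

### Seeds and constraints

A *canonical seed* is a helix of exactly `seedBP` consecutively stacked
pairs — no loops inside the seed. When a seed is required (both shipped
presets require one), every reported interaction must contain at least
one seed passing all active seed filters:

| constraint | meaning | default / recommended |
|---|---|---|
| `seedBP` | consecutive pairs in the seed | 7 / 7 |
| `seedNoGU` | forbid GU wobble pairs in seeds | off / on |
| `seedMaxE` | bound on seed energy incl. both seed-site EDs (kcal/mol) | unset / unset |
| `seedMaxEhybrid` | bound on seed hybridization energy alone | unset / unset |
| `seedMinPu` | minimal unpaired probability of *both* seed regions | unset / 0.001 |
| `intLenMax` | maximal covered length per RNA (nt) | 150 / 60 |
| `maxLoop` | maximal unpaired bases per strand per interior loop | 16 / 8 |
| `intMaxE` | maximal overall energy E (kcal/mol) | 0 / 0 |
| `intMinPu` | minimal unpaired probability of both full sites | unset / 0.001 |

Seed energy filters evaluate the seed as a standalone duplex (initiation
plus its stacks plus end penalties); `seedMinPu` applies to the exact
`seedBP`-long region on each RNA independently, and `intMinPu` likewise
to both full interaction sites. Where a tool could demand that *all*
seeds of an interaction pass the filters, `seedscan` requires *at least
one* passing seed — the natural reading for a containment constraint,
and the cheaper one to verify.

### The search

With a seed required, prediction is seed-anchored: enumerate all passing
seeds (ascending positions), then for each seed run two dynamic
programs that compute, for every feasible left/right extension endpoint,
the minimal added hybridization terms. The two sides are coupled only
through the accessibility penalties of the final regions, so the exact
combination step scans left-cell/right-cell pairs with admissible
branch-and-bound bounds: $ED$ is monotone non-decreasing under region
growth, so boundary EDs of partial regions under-estimate the final
penalty, and cumulative minima of the opposing side's hybridization
terms close the bound. Seeds are processed in ascending seed-energy
order so a strong incumbent prunes aggressively; pruning uses a strict
$10^{-9}$ margin so exact ties are still compared and resolved
lexicographically (smallest RNA1 start, then RNA2 start, then shortest
regions). The loop transitions inside the extension DPs exploit that the
loop cost depends only on the total gap: predecessors for a fixed total
gap lie on one anti-diagonal in a sliding window, so a monotone deque
yields the minimum in amortized constant time, reducing the per-cell
work from $O(\mathrm{maxLoop}^2)$ to $O(\mathrm{maxLoop})$.

Without a seed requirement the package falls back to an exact
anchor-scan DP over all leftmost pairs. This is intended for small
inputs (verification, exploratory use); the screen configurations of
interest always require seeds.

`predict_interaction_bruteforce()` re-solves the identical problem by
exhaustive enumeration of all non-crossing pair sets with direct
re-summation of every term, sharing no search code with the DP. The
central correctness property — identical optimal $E$ under randomized
constraint configurations spanning every flag — is exercised on a
thousand random instances in the test suite.

## The benchmark pipeline

Target windows are extracted from a genome FASTA and GFF3 annotation:
for each protein-coding gene (CDS features; multi-CDS loci use the
5'-most start), the region from 200 nt upstream to 100 nt downstream of
the start codon on the coding strand (301 nt; truncated and flagged at
contig ends), transcribed to RNA. For each sRNA, every window is scored
with `predict_interaction()` and targets are ranked by ascending $E$
(no-interaction targets last, ties by target id). Recovery counts the
literature-verified sRNA–target pairs whose target ranks within the
top N (default 100) for its sRNA — a lower bound on true positives among
the top predictions. `sweep_configs()` compares configurations by total
recovery, recovery relative to a reference configuration, and wall-clock
ratio (reported for orientation only; runtimes are hardware-dependent
and never asserted in tests). Accessibility profiles are precomputed
once and shared across configurations, mirroring screen practice of
excluding accessibility precomputation from per-configuration cost.

## The synthetic fixture

Because genome-scale screens need external downloads and cluster-scale
compute, the package ships a deterministic generator of desk-scale
fixtures emulating the screen's structure: by default 15 sRNAs (60 nt)
shared by two synthetic organisms — as homologous sRNAs are in real
two-organism screens — with 100 start-codon windows (301 nt) per
organism, of which 40 per organism carry a planted site: a subsequence
reverse-complementary to a fixed source region of the verified sRNA
(9–12 nt, drawn per sRNA), placed just upstream of the start codon where
real sRNA sites cluster. A toy genome plus GFF3 per organism reproduces
the windows through the extraction path, and a verified-pair TSV lists
the planted associations.

When `planted_site_accessible` is set (the default), sites are embedded
in low-structure context by construction: sRNA backgrounds are G-free
with a C/A-rich source region (so the source region cannot form a
single strong intramolecular pair), target sites receive pure-A/U
flanks, and the generator enforces an accessibility floor — every
seed-sized window of a planted site must reach $P^u \ge 0.005$, five
times the customary screening threshold of 0.001, redrawing the random
background otherwise. This makes the flag's contract real rather than
aspirational: planted sites are genuinely accessible, so they are
recoverable under accessibility-constrained configurations, and the
expected qualitative trends (full planted-site recall at loose
constraints; recovery plateau across `intLenMax` 60/100/150 when
planted interactions fit in 60 nt; recommended preset recovering at
least as many verified pairs as the default) are properties of the
construction, not accidents of a seed.

What the fixture does *not* emulate: real genomic sequence composition
(decoys are i.i.d. nucleotides at a configurable GC content), repeat
structure, operon organization, 5'-UTR regulatory elements, or
biologically calibrated effect sizes. Passing the fixture-level checks
therefore demonstrates that the pipeline's machinery behaves correctly
and that the constraint trends have the expected direction on
accessible planted sites — not that recovery percentages transfer
quantitatively to real screens. Generation is bit-stable: a fixed
generator (Mersenne-Twister with explicit seeding, global RNG state
restored afterwards) makes identical specs produce byte-identical
files.

## Numerical choices and edge cases

* Gas constant 0.0019872 kcal/(mol·K); natural logarithm in $ED$
  (thermodynamic convention); default temperature 310.15 K.
* $P^u$ floored at $10^{-10}$ before logs; partition functions carried
  in extended (long double) precision, which keeps 300-nt windows in
  range without rescaling.
* Monotonicity validation on profile input tolerates $10^{-9}$; profile
  round-trip through TSV preserves probabilities to the same tolerance.
* Tie-breaking is fully specified (energy, then 5'-most RNA1 start,
  RNA2 start, shortest regions) so rankings are deterministic and
  permutation-invariant; equal-energy targets order lexicographically.
* Degenerate inputs: sequences too short to pair give all-ones
  profiles; empty pair lists, crossing pairs, non-canonical pairs,
  ambiguity codes, duplicate FASTA ids, and malformed parameter or
  profile files are rejected with specific errors rather than repaired.
* Problem sizes in the shipped tests: oracle equivalence on 1000 random
  pairs of 8–14 nt; accessibility exactness on sequences up to 12 nt
  (the exhaustive-enumeration regime); the full fixture screen at
  15 × 200 sRNA–target combinations under four configurations.

## Known limitations

* The compact energy tables reproduce orderings and magnitudes, not any
  published parameter set; absolute energies should not be compared
  against other tools' outputs.
* Single-site predictions only: no suboptimal interaction lists, no
  multi-site or pseudoknotted interactions.
* Global folding of each input sequence for accessibility; no
  plfold-style scanning windows.
* The seedless search path is exact but quadratic in both window areas
  and meant for small inputs.
* Reported runtime ratios depend on hardware and load; only their
  qualitative ordering is meaningful.
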