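# seedscan

Accessibility-based RNA–RNA interaction prediction with a full suite of
seed and interaction constraints, plus the benchmarking pipeline used for
bacterial sRNA target screens.

## The problem

Small regulatory RNAs (sRNAs) in bacteria repress or activate mRNAs by
base pairing, usually near the start codon. In silico target screens rank
every candidate mRNA by the stability of its best predicted interaction
with the sRNA — but an unconstrained duplex search drowns in false
positives. Practical screens therefore combine three ingredients:

1. **Hybridization energy** `Eh`: the nearest-neighbor free energy of the
   intermolecular duplex (stacking dyads, interior loops/bulges, duplex
   initiation, AU/GU helix-end penalties).
2. **Accessibility penalties** `ED = -RT ln(Pu(i..j))`: the energetic
   price of freeing each interaction site from intramolecular structure,
   where `Pu(i..j)` is the exact Boltzmann probability that region `i..j`
   is unpaired in the single-molecule ensemble (McCaskill-style
   partition functions with region-unpaired constraints).
3. **Seed and interaction constraints**: every reported interaction must
   contain a *canonical seed* — `seedBP` consecutively stacked base
   pairs — optionally filtered by GU-prohibition, seed energy thresholds
   (`seedMaxE`, `seedMaxEhybrid`) and seed-site accessibility
   (`seedMinPu`); the overall interaction is constrained by length
   (`intLenMax`), loop size (`maxLoop`), energy (`intMaxE` — only
   net-stabilizing interactions with `E <= 0` are reported by default)
   and site accessibility (`intMinPu`).

The reported interaction minimizes the overall energy

```
E = Eh + ED1(i..j) + ED2(k..l)
```

over all constraint-satisfying non-crossing duplexes. `seedscan`
implements this search exactly (verified against brute-force enumeration
oracles), along with the surrounding screen machinery: start-codon
window extraction from genome + GFF3, per-sRNA target ranking, top-N
recovery of literature-verified pairs, configuration sweeps, and a
deterministic synthetic fixture generator so that the whole pipeline is
testable offline.

Two constraint presets are shipped: `"default"` (7-bp seeds, GU allowed,
`intLenMax` 150, `maxLoop` 16, `intMaxE` 0) and `"recommended"` (7-bp
seeds without GU pairs, `seedMinPu` 0.001, `intLenMax` 60, `maxLoop` 8,
`intMinPu` 0.001), the constraint set found to maximize verified-target
recovery in systematic screening.

## Worked example

```r
library(seedscan)

srna <- c(RyhB_like = "AAUGCAAUUUUCAACCAGCCGCAAGGAAUAAUAACUGGAAACAAAUUUGAAUUGAAAACG")
target <- c(sodB_like = paste0(
  "AAGUAAUUAAAUUGGCUUUUUCUCAUCUCAAUUUUAGCAACUGGUUGAAAAUUGCAUUUU",
  "CAUCUUUAAAAUCAAUUUUACGUAAAAUCGUUCUACCAAUUGAUUAAGGCUUUUUACAAC",
  "AUGUCAUUCGAAUUACCUGCAUUACCUUAU"))

cfg <- prediction_preset("recommended")
predict_interaction(srna, target, cfg)
#> RNA-RNA interaction RyhB_like[1..9] : sodB_like[50..58]
#>   E = -2.607 kcal/mol (Eh = -7.800, ED1 = 1.814, ED2 = 3.378)
#>   9 base pairs: (((((((((&)))))))))
#>   seed: [1..7] : [52..58]
```

The sRNA's first 9 nt pair with target positions 50–58 (RNA2 coordinates
run antiparallel to RNA1). The duplex alone contributes −7.8 kcal/mol;
opening the two sites costs 1.8 + 3.4 kcal/mol of accessibility penalty,
leaving a net interaction energy of −2.6 kcal/mol. The reported seed is
the 7-pair canonical helix that passed all seed filters.

Screening a synthetic fixture and counting recovered verified pairs:

```r
fx <- generate_fixture(fixture_spec(n_srna = 3, n_targets_per_organism = 20,
                                    n_verified = 6, organisms = "demo",
                                    rng_seed = 7), tempdir())
rk <- rank_targets(fx$srnas["sRNA01"], fx$targets_by_organism$demo, cfg)
head(rk, 5)
#>   target_id          E rank
#> 1 demo_g001 -18.033209    1
#> 2 demo_g004 -14.598298    2
#> 3 demo_g011  -7.126608    3
#> 4 demo_g015  -7.004764    4
#> 5 demo_g013  -6.776279    5

run_benchmark(fx$srnas, fx$targets_by_organism, cfg, fx$verified,
              top_n = 5)$recovery
#> Recovery report: 6/6 verified pairs within top-5
```

`demo_g001` and `demo_g004` carry planted sites complementary to
`sRNA01`; both rank ahead of all decoys, and all six verified pairs of
the fixture are recovered within the top 5 predictions per sRNA.

## Command line

A thin CLI wraps the same functions (installed under `exec/`):

```sh
seedscan predict -q srna.fa -t targets.fa --preset recommended -o out.csv
seedscan bench --genome g.fa --gff g.gff3 --srna s.fa --verified v.tsv -o outdir/
seedscan fixture --seed 1 -o fixturedir/
seedscan acc -i targets.fa --max-len 150 -o accdir/
```

All outputs carry a provenance header (`#config.*`, input checksums);
coordinates are 1-based inclusive throughout.

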