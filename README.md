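# nestedmir

Structural analysis of **nested miRNA genes** — fold-back pri-miRNA
precursors that fully contain a second miRNA precursor, with both hairpins
releasing independent, non-overlapping mature miRNAs from the same stem. The
package targets the plant MIR159 family, whose *Arabidopsis* MIR159a stem
carries two stacked miRNA/miRNA\* duplexes plus a loop-distal small RNA,
named by duplex index from the base of the stem:
`miR159a.1-5, miR159a.2-5, miR159a.3, miR159a.2-3, miR159a.1-3`.

It is written for people studying miRNA gene architecture and evolution who
need the computational pipeline behind such an analysis to be reproducible:
every threshold is explicit and echoed into run metadata, every stochastic
step is seeded, and every stage is testable against planted ground truth.

## What it does

* **seqio** — miRBase-dialect hairpin/mature FASTA (three-letter species
  codes, T→U normalization), GFF3 loci, 1-based-inclusive genomic vs
  0-based-half-open local coordinates (e.g. the MIR159a locus printed in
  reverse order, 27,713,700–27,712,893, normalizes to the minus strand and
  spans `27712893 + 808 - 1` → **808 bp**).
* **structure** — `fold_maxpair()`: deterministic base-pair maximization
  (Watson–Crick + GU, `min_loop = 3`) with an Rcpp core, checkable against a
  brute-force oracle; `ingest_dotbracket()` for externally computed (RNAfold)
  structures; arm/loop decomposition; elongated-stem vs branched topology.
* **nested** — mature mapping, miRNA\* inference with the 2-nt 3'-overhang
  convention (`overhang = 0` for exact-partner mode), strict-containment
  nestedness over non-overlapping duplexes, sibling naming, cross-species
  summaries.
* **evolution** — per-column conservation profiles, region
  conserved/specific calls (thresholds 0.75/0.50, configurable), p-distance
  and Jukes–Cantor correction, hand-written Saitou–Nei neighbor joining with
  a deterministic tie-break (newick via `ape`), monocot/dicot two-group
  split test.
* **promoter** — TSS-relative truncation (3.0…0.2 kb series) and deletion
  constructs (`delta858-862` removes exactly the 5-bp GGATA box), IUPAC
  cis-element scanning (MybSt1 `GGATA`, TATA, CAAT built in).
* **qpcr** — 2^−ΔCt relative quantification, replicate means/SEM, folds with
  the baseline group set to 1, Student's t / one-way ANOVA with the usual
  significance stars.
* **synthetic_data** — seeded generators with serialized ground truth for
  hairpins (planted duplexes), species panels (region-specific substitution
  rates, optionally along a tree), promoters (planted motifs, repaired
  background) and Ct tables (planted folds).
* **pipeline** — `run_pipeline()` orchestrates
  ingest → fold → detect → summarize → evolve with a stage manifest and
  deterministic outputs.

## Worked example

```r
library(nestedmir)

# a synthetic MIR159a-like precursor with known ground truth
hp <- make_hairpin(hairpin_spec(seed = 1, id = "ath-MIR159a"))
span <- map_mature(hp$precursor$sequence, hp$truth$matures$sequence[1])
dup  <- infer_star(hp$structure, span, precursor_id = "ath-MIR159a")
print(dup)
#> <mir_duplex> ath-MIR159a mature [5,26) on 5arm, star [148,169); paired 1.00, 0 mismatches

inv <- name_siblings(detect_nested("ath-MIR159a", hp$structure, list(dup)))
# ... with all three mature records (see analysis/02_detect_nested.R) the
# inventory is nested and the names read:
#>              name start end         kind
#> 1 ath-miR159a.1-5     5  26 sibling_5arm
#> 2 ath-miR159a.2-5    35  56 sibling_5arm
#> 3   ath-miR159a.3    60  80  loop_distal
#> 4 ath-miR159a.2-3   118 139 sibling_3arm
#> 5 ath-miR159a.1-3   148 169 sibling_3arm

inclusive_length(genomic_locus("chr1", 27713700, 27712893))   # reverse order
#> [1] 808
```

The numbers mean: the first duplex's mature spans precursor positions 5–25
(0-based, half-open) on the 5' arm, its star 148–168 on the 3' arm with the
2-nt 3' overhang applied; the five named small RNAs follow the
basal-to-distal naming scheme; and the real MIR159a locus, printed in
reverse order because the gene is on the minus strand, is 808 bp inclusive.

## The analysis workflow

The numbered scripts under `analysis/` are thin drivers over the package and
write their tables under `results/`:

| script | what it reports |
|---|---|
| `01_simulate.R` | generates all synthetic study inputs (6 precursors, a 12-species panel, a 3-kb promoter, Ct tables) under `results/inputs/` |
| `02_detect_nested.R` | `5 of 6 precursors nested`, the five sibling names, the 808-bp / 183-bp locus arithmetic |
| `03_phylogeny.R` | conservation by region (duplex > loop > flank), duplex-region conserved/specific calls, JC69 distances, NJ tree |
| `04_promoter.R` | MybSt1 hits per truncation/deletion construct (2 on fragments ≥ 1 kb; 1 after each single deletion; 0 after the double) |
| `05_qpcr.R` | relative expression with the wild type set to 1 (planted folds 1/6/2 recovered), t tests and ANOVA with stars |
| `06_mirbase_reproduction.R` | the registry-scale census, only if miRBase release 21 files are present under `data-raw/mirbase21/` |

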