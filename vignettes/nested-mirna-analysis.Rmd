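---
title: "Detecting and analysing nested miRNA structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing nested miRNA structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestedmir)
```

## The problem

Plant miRNA genes are transcribed as long fold-back precursors from which
Dicer-like enzymes release a miRNA/miRNA* duplex: the mature small RNA and
its partially complementary partner on the opposite arm of the hairpin,
typically left with 2-nt 3' overhangs. Some precursors — the MIR159 family is
the canonical case — carry a *nested* architecture: the pri-miRNA fully
contains a second miRNA precursor, and the two hairpins release independent,
non-overlapping mature miRNAs from the same stem. On *Arabidopsis* MIR159a
the stem carries two stacked duplexes plus a single loop-distal small RNA,
named by duplex index counted from the base of the stem: `miR159a.1-5`,
`miR159a.2-5`, `miR159a.3`, `miR159a.2-3`, `miR159a.1-3` in 5'-to-3'
precursor order.

`nestedmir` implements the full analysis around that observation: reading
miRBase-dialect sequence files, folding or ingesting stem-loop secondary
structures, locating duplexes and deciding nestedness, naming siblings,
quantifying cross-species conservation and reconstructing a neighbor-joining
phylogeny, dissecting promoters with exact TSS-relative bookkeeping, and
computing qPCR relative expression. A synthetic-data module generates every
input class with known ground truth, so each stage is testable end to end
without downloads. The repository is organised as an analysis workflow: the
numbered scripts under `analysis/` are thin narrative drivers over the
package functions, which also back the test suite and
`scripts/acceptance.R`; no separate shell tool is shipped because the
functions and scripts *are* the interface.

## Secondary structure

The built-in folder, `fold_maxpair()`, maximises the number of legal base
pairs (Watson-Crick plus GU wobble, the standard set for plant miRNA
hairpins) over all pseudoknot-free structures, subject to a minimum hairpin
loop of `min_loop = 3` unpaired bases. This is a deliberate design choice:
base-pair maximisation is exactly checkable against a brute-force
enumeration oracle, which the test suite exercises on hundreds of random
short sequences, whereas a thermodynamic (minimum-free-energy) structure
depends on parameter sets, temperature and dangle options that a published
analysis rarely pins down. Externally computed MFE structures (e.g. RNAfold
output) are therefore the supported route for exact replication and enter
through `ingest_dotbracket()`, which validates the same invariants: balanced
non-crossing brackets, the pair table an involution, minimum loop size, and
legal pairs only. No attempt is made to reproduce any specific RNAfold
output, since its parameters are not knowable from a methods section.

Determinism: the traceback prefers pairing a position over leaving it
unpaired at equal pair count, and among equally optimal partners takes the
smallest admissible one. Ties therefore never introduce run-to-run
variation.

`decompose()` labels every position as `5arm`, `loop`, `3arm` or `flank`:
the terminal loop is found by following the 5'-most helix path from the
outermost pair, bulges stay on their arm, and unpaired ends are flanks.
`classify_topology()` separates single *elongated stems* (no multiloop;
internal loops and bulges allowed) from *branched* fold-backs (at least one
internal node spawning two or more helices) — the structural difference
observed between monocot and dicot MIR159a stem-loops.

## Duplexes, nestedness and naming

A mature record is mapped onto its precursor by exact substring match
(`map_mature()`, leftmost match, multiplicity warned). `infer_star()` takes
the partner interval of the mature's paired positions and shifts it
downstream by `overhang = 2` nt — the Dicer 2-nt 3'-overhang convention —
clipping at the precursor ends; `overhang = 0` gives exact-partner mode, so
the convention never silently changes results. A mature with fewer than
`min_duplex_pairing = 0.6` of its positions paired is "not on a stem": in
the pipeline such records become *loop-distal* candidates rather than duplex
anchors. The 0.6 pairing threshold and the `max_mismatches = 7` acceptance
bound are conventions, not published values; both are configurable and are
echoed into every run's metadata so reported counts are interpretable.

`detect_nested()` operationalises the nested definition: an inventory is
nested when at least two accepted duplexes stand in strict containment — the
inner duplex's mature and star spans both lie strictly inside the region
enclosed by the outer duplex (outer mature start to outer star end) — with
all mature/star spans pairwise non-overlapping. Overlapping duplex pairs are
rejected from the nested relation and reported, never fatal. A loop-distal
RNA is emitted only when an annotated mature maps strictly inside the
innermost enclosed region without touching any duplex span; a
structure-only mode (emitting loop-distal RNAs without mature evidence) was
considered and not implemented, because nothing in the data distinguishes
such a span from any other near-loop sequence.

`name_siblings()` numbers duplexes `.1, .2, ...` from the basal (outermost)
duplex, suffixes the 5'-arm sibling `-5` and the 3'-arm sibling `-3`, and
gives a loop-distal RNA the next index with no arm suffix. Sorted by span
start, names read 5'-arm ascending, then the loop-distal RNA, then 3'-arm
descending — the five-name pattern above. Where published running text and
figure caption disagree on one sibling's name, the caption's internally
consistent five-name set is the canonical scheme here.

## Conservation and phylogeny

Alignments are *ingested* (aligned FASTA); running T-Coffee or MUSCLE is
glue, not method, and out of scope. `conservation_profile()` reports
per-column identity as the modal-residue frequency among non-gap characters,
with the gap fraction kept separate (an all-gap column has identity 0 by
convention). `region_conservation()` compares each member to the region
consensus and calls it conserved at identity >= 0.75 or specific below 0.50.
These two thresholds are the package's own defaults — the published
"conserved" and "specific" percentages come with no stated cutoffs — and are
echoed in the output, which is why such percentages are reproducible only
*relative to* a declared threshold pair.

`pdistance()` computes p-distances over columns where both rows are non-gap,
with optional Jukes-Cantor correction `d = -(3/4) log(1 - 4p/3)`; saturated
pairs (`p >= 0.75`) are set to a declared ceiling with a warning rather than
silently dropped. `neighbor_joining()` is a hand-written Saitou-Nei
implementation kept deliberately simple so its determinism is auditable: Q
ties are broken by the lexicographically smallest pair of subtree labels,
and negative branch-length estimates are clamped to zero with the raw values
recorded. On additive matrices NJ is exact, which gives the suite a sharp
oracle: distances derived from random binary trees must return the same
topology and path lengths to 1e-9. `ape` serves as newick serialiser and as
an independent cross-check (`ape::nj` agreement on additive inputs), never
as the implementation. The published methods name NJ while the discussion
mentions a maximum-likelihood tree; NJ is what is implemented, ML is out of
scope, and the discrepancy is simply noted. `two_group_split()` answers the
monocot/dicot question as a clean topological predicate: does any edge
bipartition equal the label bipartition?

## Promoter dissection

Positions are TSS-relative: -1 is the base immediately upstream of the
transcription start site. Whether coordinates are anchored at a mapped TSS
or at the TATA box is ambiguous in published figures, so the reference point
is simply whatever position the user supplies as the 3' end of the promoter
sequence. `truncate_promoter()` keeps the L bases nearest the TSS;
`delete_span(p, a, b)` removes original positions `-max(a,b)..-min(a,b)`
inclusive — deletions are specified in original coordinates (construct names
like delta858-862 are), so two deletions compose in either order. Hit
positions are reported in current-construct coordinates: downstream
positions are unchanged by a deletion, upstream ones are renumbered. The
canonical MybSt1 deletions are the 5-bp spans matching the GGATA boxes at
-858..-862 and -946..-950 (the motif length forces 5 bp; published
off-by-one variants are accepted as explicit coordinates), and the default
truncation series covers both printed lengths of the short fragment (0.6 and
0.7 kb) plus the 173-bp minimal construct. `scan_motifs()` is an exact IUPAC
consensus scan (Biostrings matching underneath) over a small built-in
PLACE-style table — MybSt1 `GGATA`, TATA box, CAAT box — or any user table;
the full PLACE database is not redistributed, the scan engine is the point.

## qPCR quantification

`relative_quantity()` is the 2^-deltaCt measure (not delta-deltaCt — the
literal reading of the methods), `summarize_replicates()` averages
per-replicate RQs, takes the SEM over the (typically three technical)
replicate RQs, and divides by the baseline group's mean so the wild type is
exactly 1. Shifting every Ct by a constant leaves all RQs unchanged, which
the suite tests as a property. `group_tests()` delegates to Student's t test
(two groups, equal variances, two-sided) or one-way ANOVA, with significance
stars at 0.05/0.01/0.001; degenerate all-identical groups return t = 0,
p = 1 explicitly instead of NaN. Amplification-efficiency correction and
standard curves are out of scope.

## The synthetic generators: what they emulate, and what they do not

`make_hairpin()` builds a fold-back whose 3' arm is the reverse complement
of the 5' arm except at planted mismatch positions; planted duplexes sit on
the 5' arm, so any two non-overlapping planted duplexes are strictly nested
by construction. The loop-distal span's partner region is de-paired at
alternating positions (paired fraction 0.5, below the 0.6 acceptance
threshold), which is what makes a loop-distal RNA recoverable *as* a
loop-distal RNA rather than a third duplex — mirroring the weakly paired
near-loop region where the real miR159a.3 sits. The generator re-samples the
arm sequence (bounded retries, seed-deterministic) until every emitted
mature occurs exactly once in the precursor and the maximum-pairing fold
covers all mismatch-free duplex positions, so detection on generated
instances is well-posed by construction rather than by luck. Defaults mirror
the MIR159a architecture: 80-nt arms, 12-nt loop, two 21-nt duplexes at arm
offsets 5 and 35, one 20-nt loop-distal RNA.

`make_panel()` evolves a species panel from an ancestor with region-specific
per-site substitution rates (defaults 0.02 duplex / 0.10 loop / 0.20 flank,
encoding the observed constraint gradient), either independently per species
(star tree; the rate is the per-site substitution probability) or along a
supplied tree with Jukes-Cantor edge probabilities
`(3/4)(1 - exp(-(4/3) rate t))`. Evolution is indel-free by default, so the
true alignment is trivially known and conservation tests never depend on an
external aligner. `make_promoter()` plants motifs at stated upstream offsets
on a uniform background and destroys accidental occurrences (both strands)
by point repair until a scan recovers exactly the planted set; the default
layout is the two-GGATA arrangement at -862 and -950. `make_ct()` fixes the
reference Cts and sets target Cts to `ct_ref - log2(fold) + N(0, sigma)`.

What passing tests on these inputs do *not* show: real hairpins are not
complementarity-perfect, real panels contain indels and alignment error,
real promoters have biased composition, and real Ct noise is not Gaussian
with a fixed reference. The generators certify the algorithms, not the
biology.

## Problem sizes and numerical choices

The test and acceptance batteries run at sizes chosen to make each check
sharp yet quick: 200 random sequences of length at most 14 against the
brute-force fold oracle; 50 random additive 5-8 taxon trees for NJ (path
lengths to 1e-9); 100 seeded hairpins (two- and three-duplex architectures,
with and without a loop-distal RNA) for planted recovery, required to be
100/100 exact; 100 seeded 6-taxon panels of 2000 nt with per-branch
divergence 0.02-0.10 substitutions/site, requiring topology recovery in at
least 95; and 200 seeded Ct tables (sigma = 0.2, triplicates) requiring the
planted twofold change back within 10%. Floating-point ties in the NJ Q
matrix are compared with a 1e-12 relative tolerance before the lexicographic
tie-break; branch lengths are serialised at 15 significant digits.

## Reproducing the registry-scale counts

The published census — 82 of 88 MIR159 precursors nested across 36 land
plant species, six nested groups with 18 mature miRNAs in *Arabidopsis*,
miR829a.1 at 23 nt and miR159a.3 at 20 nt — requires the miRBase release 21
hairpin/mature files, which this repository does not redistribute.
`analysis/06_mirbase_reproduction.R` (and the corresponding acceptance test)
runs `reproduce_mirbase_counts()` and `species_nested_scan()` when those
files are placed under `data-raw/mirbase21/`; without them the test reports
the missing inputs and fails rather than pretending. Those counts are
sensitive to the structure source (built-in folder vs external RNAfold
dot-brackets) and to the acceptance thresholds, all of which are echoed next
to the counts.

## Known limitations

The folder ignores thermodynamics, so on real sequences its structures can
differ from MFE structures — use external dot-brackets where fidelity
matters. Nestedness is decided purely from spans on one precursor; small-RNA
read-stack evidence and expression-based validation of siblings are out of
scope. Conservation percentages depend on declared thresholds. NJ gives no
support values, and ML trees are not implemented. The promoter scanner does
exact consensus matching only — no PWMs, no de-novo motif discovery.
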