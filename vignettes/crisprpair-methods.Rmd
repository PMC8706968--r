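---
title: "Profiling Cas12a editing activity with paired guide-target libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling Cas12a editing activity with paired guide-target libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprpair)
```

## The assay this package models

Cas12a (Cpf1) effectors are profiled at scale by integrating *self-cleaving
paired guide-target constructs* into the genome: each lentiviral construct
carries both a crRNA expression cassette and the matching 42-nt synthetic
target, so the guide meets its target in cis in every transduced cell. After
effector delivery and a week of outgrowth, the integrated cassette is
amplified and deep-sequenced; editing shows up as indels in the target half
of the amplicon, while the guide-encoding half plus a 12-nt barcode identify
which library member the read came from.

The sequenced amplicon mirrors the 142-nt synthesized oligonucleotide:

| element | width | purpose |
|---|---|---|
| forward constant | 20 | amplification primer site |
| scaffold handle  | 19 | crRNA direct-repeat stem-loop |
| spacer           | 23 | guide / protospacer sequence |
| poly-T           | 6  | U6 transcription terminator |
| barcode          | 12 | unique pair identifier |
| target           | 42 | PAM + protospacer + downstream context |
| reverse constant | 20 | amplification primer site |

`crisprpair` implements the full desk-side computation: library design,
a synthetic read generator with known ground truth, indel calling with
control-differential background subtraction, and downstream activity and
PAM-preference profiling, plus the Poisson MOI arithmetic used to plan the
lentiviral transduction.

## Library design

`design_library()` scans input sequences on both strands for PAM-adjacent
protospacers (`scan_protospacers()`), using IUPAC-degenerate patterns
(`expand_pattern()`, `matches_pam()`). Presets mirror the three published
pools: `lib-a` = TTTV (canonical), `lib-b` = {TTCV, VTCV, VCTV, VCCV, VTTV}
(C-rich), `lib-c` = {TRTN, NTTT}. Guides are filtered to 20-80% GC with no
TTTT run (a T-run would terminate U6 transcription early), and the top 10
candidates per gene are kept. Because the original web-tool guide score is
not reproducible, ranking is by distance of spacer GC from 50% (ties:
`pam_start`, then strand) - deterministic and favouring mid-GC guides.

The 42-nt target window is PAM (4) + protospacer (23) + downstream genomic
context (15). Barcodes are drawn at minimum pairwise Hamming distance 3 with
no 4-base homopolymer; the distance constraint is this package's own
hardening (the assay only requires uniqueness) so that a single sequencing
error cannot convert one barcode into another.

Coordinates are 0-based half-open throughout; minus-strand sites report
their sequences 5'->3' on the minus strand and their `pam_start` as the
plus-strand offset of the leftmost PAM base.

## The read generator

`generate_dataset()` emits, for every pair, `depth_per_pair` experimental
reads and the same number of no-effector control reads. Editing is a
per-molecule Bernoulli draw with probability `pam_activity[pam]` from the
`effector_model()`, or a per-pair rate from the optional `edit_rates`
override — used to give each guide an intrinsic activity (a property of the
pair, shared between simulated replicates), which is what makes replicate
correlations meaningful. Edited molecules are repaired by one of two pathways:

* **MMEJ** (probability `mmej_weight`, default 0.5 - the true ratio is not
  known quantitatively, so it is an explicit free parameter): a deletion
  that collapses two identical flanking k-mers (k >= 2,
  `find_microhomologies()`), restricted to deletions spanning the staggered
  cut, drawn with probability proportional to microhomology length.
* **NHEJ**: a deletion covering one of the two nicks with geometric(0.3)
  length truncated at 20, or (probability 0.25) a 1-3-nt random insertion
  at a nick.

The staggered cut is placed at target offsets (22, 27): the PAM occupies
positions 0-3 and Cas12a nicks ~18 and ~23 nt distal of it, the canonical
geometry. All of these are `effector_model()` arguments.

### Background noise

The noise model reflects *where* errors arise in this assay, because that
determines whether control subtraction can remove them:

1. **Clonal library variants** (`variant_rate`, Poisson mean 0.3 per pair;
   abundance 0.5-2%): oligo-synthesis indels live in the construct pool.
   The control group is the same established cell library without effector
   delivery, so variant haplotypes and their frequencies are *shared*
   between experimental and control reads.
2. **Systematic substitution errors** (`substitution_rate`, default 1e-3
   per base): sequencing substitution errors concentrate at run-specific
   error-prone positions; the generator draws 3 pair-specific sites that
   carry the whole substitution-rate mass, again shared between groups.
3. **Stochastic artifacts** (`background_indel_rate`, default 1e-4 per
   read): i.i.d. indel miscalls of length <= 3 anywhere in the read.

Each read carries at most one background lesion; co-occurrence (~0.2% of
reads at the default rates) is neglected. A purely i.i.d. error model would
make control subtraction ineffective by construction (an i.i.d. error type
almost never recurs in a finite control), which is not how the assay
behaves; the shared-background components are what make the
control-differential design sound. What the generator does *not* emulate:
chromatin-context effects on integrated copies, PCR duplication and
jackpotting, quality-score structure, paired-end overlap, or read trimming.
Passing recovery tests on these simulations therefore validates the calling
logic, not robustness to every real-world artifact.

## Indel calling

Reads are demultiplexed by *exact* match of the crRNA-encoding region
(handle + spacer, at its fixed offset) and the 12-nt barcode: a recognized
barcode with a mismatched crRNA region is counted `invalid` (editing through
an imperfect guide is not interpretable), an unrecognized barcode is
`unassigned` (one reverse-complement rescue attempt is made). Barcode error
correction is deliberately off to mirror strict identification.

Assigned reads have their target region aligned end-to-end against the
42-nt reference (match +2, mismatch -4, gap open -6, gap extend -1). Among
score-equivalent alignments the caller reports a canonical one: fewest
indel events, then fewest substitutions, then all gaps at their lowest
score-equivalent coordinate. The parsimony rule matters because, under this
scoring, one merged gap plus a substitution ties exactly with two split
gaps; without a deterministic convention the same molecule could be
catalogued as two different repair types. The canonicalization is exact (a
dynamic program over the (score, events, substitutions) triple, implemented
in C++), and the test suite checks it read-for-read against a brute-force
enumerator of all co-optimal alignments.

Classification is two-round:

1. indels overlapping the 42-bp primary frame (the whole target window by
   default) are recognized;
2. a read whose recognized indels are all small (<= 3 bp) **and** all
   outside the 8-bp secondary frame is re-classified as background. The
   secondary frame is centred on the midpoint of the two nicks
   ((22+27+1)/2, giving [21, 29)); the "middle of the cleavage site" is not
   defined more precisely by the assay, so the frame is configurable.

Single-base substitutions inside the primary frame count as valid editing
by default (`substitution_policy = "count_in_frame"`); recurring
sequencing-error types are then removed by control subtraction. Because
that reading of the assay could be disputed, `"ignore"` is available and
switches substitution-only reads to unedited.

Per pair, edited reads are grouped into repair types keyed by their exact
event list and serialized in the catalogue format `[(20, 6)]:111` (a 6-bp
deletion at positions 20-25, position 0 = 5' end of the PAM, seen in 111
reads); insertions carry an `I` suffix with the inserted bases and
substitutions an `S` tag. `subtract_background()` removes every repair type
whose event list also occurs in the *same pair's* control catalogue
(per-pair matching is the stricter reading of "corresponding control") and
re-counts those reads as unedited. The final statistic is

    indel frequency = edited / (edited + unedited)

with background-filtered reads kept in the denominator (they were sequenced
and judged unedited; a flag drops them instead), no further normalization,
and pairs at or below `min_reads = 300` total flagged excluded.

## Downstream profiling

`summarize_by_pam()` averages per-pair frequencies over the expansion of
each degenerate PAM group (excluded pairs dropped, never imputed; both mean
and median are emitted because reports mix the two). `classify_pathway()`
calls a repair type MMEJ iff it is a single deletion reproducible by
collapsing a flanking repeat of length >= 2 - an operational definition;
mixed-event types count as NHEJ. `compare_two()` is a two-tailed
Mann-Whitney U with exact permutation p-values (correct under ties) up to
pooled n = 10 and a tie-corrected normal approximation beyond;
`compare_many()` is a tie-corrected Kruskal-Wallis H followed by Dunn's
pairwise z tests with Bonferroni adjustment by default (the adjustment
behind the original Prism analysis is not named, so it is configurable).
`rank_effectors()` splits effectors at a 20% mean-frequency threshold - a
reporting convention, not inference.

## Transduction planning

Under the Poisson model, MOI = -ln(1 - P1) where P1 is the
fluorescence-positive fraction; MOI 0.5-0.7 (the single-copy sweet spot)
corresponds to 39-50% positive cells. `plan_infection()` fits the titration
standard curve on the MOI scale - where virus dose is additive, unlike the
saturating positive fraction - through the origin, and scales the
recommended volume by cell count (dose per cell is the conserved quantity).

```{r moi}
round(100 * fraction_from_moi(c(0.5, 0.7)))
plan_infection(data.frame(volume = c(5, 10, 20, 40),
                          positive_fraction = 1 - exp(-0.025 * c(5, 10, 20, 40))),
               target_moi = 0.6, cells = 4e6, titration_cells = 2e5)$volume_ul
```

## Numerical choices and test scale

* Alignment tolerances are exact (integer-valued scores); score ties are
  resolved by the canonicalization above, never by floating-point luck.
* Every random step takes an explicit seed; identical seeds give
  byte-identical outputs, including barcode assignment and read emission.
* Degenerate inputs fail loudly: unknown PAMs in an activity map, duplicate
  barcodes, substitutions at scaffold stem positions, and malformed
  repair-type strings are all errors, not warnings.
* The test suite exercises the full pipeline at 200 pairs x 1000 reads per
  pair and group (the scale at which per-pair binomial noise is ~1.5
  percentage points), and validates the aligner on 500 randomized amplicons
  against an exhaustive co-optimal enumerator. The analysis scripts under
  `analysis/` use similar sizes.

## Known limitations

* Off-target scoring ("mismatch" filters against a genome index) is out of
  scope; the design step exposes a no-op hook.
* The caller assumes the fixed amplicon layout; endogenous-site amplicons
  (arbitrary primers, variable context) are a different problem and are not
  handled.
* MMEJ classification is sequence-operational: a deletion flanked by a
  2-bp repeat is called MMEJ even though such short homologies can arise by
  chance within NHEJ products.
* Replicate correlations on simulated data are optimistic (~0.99 at depth
  1000) compared to real biological replicates, where cell-state and
  delivery variance dominate; the generator does not model that variance.
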