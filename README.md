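# crisprpair

Desk-side computation for high-throughput Cas12a activity profiling with
genome-integrated, **self-cleaving paired crRNA–target libraries**. Each
library construct carries a guide-RNA cassette *and* its matching 42-nt
target, so every transduced cell edits its own integrated target; deep
sequencing of the integrated amplicon then reads out both the guide
identity and the editing outcome. `crisprpair` implements the four
computational stages of such a screen, plus a synthetic read generator with
known ground truth standing in for real sequencing data:

1. **Design** (`design_library()`): scan reference sequences for
   PAM-adjacent protospacers with IUPAC-degenerate patterns (canonical
   Cas12a `TTTV` and the altered-PAM presets `lib-b`/`lib-c`), filter
   guides (GC 20–80%, no TTTT run), pick the top 10 per gene, assign
   distance-3 barcodes, and assemble the 142-nt oligo layout
   `fwd(20) | handle(19) | spacer(23) | polyT(6) | barcode(12) | target(42) | rev(20)`.
2. **Simulate** (`generate_dataset()`): emit experimental and no-effector
   control FASTQ reads per pair, with MMEJ deletions collapsing
   microhomologies around the staggered cut (nicks at target offsets
   22/27), NHEJ deletions/insertions at the nicks, and a background model
   (clonal library variants, systematic substitution sites, stochastic
   artifacts) whose shared components are what control subtraction can
   remove.
3. **Call** (`call_indels()`): demultiplex by exact crRNA-region + barcode
   match; align each read's target region end-to-end (match +2, mismatch
   −4, gap open −6, extend −1; canonical fewest-events / leftmost-gap
   alignment, C++); two-round frame classification (42-bp primary frame,
   then background-filtering of small indels outside the 8-bp frame
   [21, 29) around the cut midpoint); catalogue repair types in the
   `[(20, 6)]:111` format (a 6-bp deletion at positions 20–25, PAM 5′ end
   = position 0, 111 reads); remove every type that also occurs in the same
   pair's control; then

   `indel frequency = edited / (edited + unedited)`,

   with pairs at ≤ 300 reads flagged excluded.
4. **Profile** (`summarize_by_pam()`, `classify_pathway()`,
   `compare_two()`, `compare_many()`, `rank_effectors()`): PAM
   base-preference tables, MMEJ/NHEJ composition, replicate correlation,
   exact-permutation Mann–Whitney U, tie-corrected Kruskal–Wallis with
   Dunn's post hoc, and the 20% high/low activity split.

`moi_from_fraction()` / `fraction_from_moi()` / `plan_infection()` cover
the Poisson titration arithmetic (`MOI = −ln(1 − P₁)`; MOI 0.5–0.7 ⇔
39–50% positive cells) used to plan single-copy lentiviral transduction.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`01_design_library.R` → `05_plan_transduction.R`), writing tables
under `results/`. A condensed session:

```r
library(crisprpair)

genes <- setNames(replicate(25, paste(sample(c("A","C","G","T"), 600,
                                             TRUE), collapse = "")),
                  paste0("gene", 1:25))
lib <- design_library(genes, pam_patterns = pam_preset("lib-a"), seed = 1)

eff <- effector_model("strongA",
                      setNames(rep(0.39, 3), expand_pattern("TTTV")))
ds  <- generate_dataset(lib, eff, depth_per_pair = 600, seed = 2)
calls <- call_indels(ds$experimental, ds$control, lib)
head(calls$catalogue, 3)
```

Running `analysis/02`–`04` on a 120-pair canonical library at depth 600
printed:

```
strongA        mean freq 0.420 | truth r 0.991 | MAE 0.0195 | 120/120 pairs scored
weak           mean freq 0.082 | truth r 0.950 | MAE 0.0104 | 120/120 pairs scored

Effector ranking (high/low split at 20%):
   effector mean_frequency category
1 variant3R     0.43736991     high
2   strongA     0.41978611     high
3   strongB     0.35712398     high
4      weak     0.08190038     low

strongA replicate correlation: Pearson r = 0.987 (n = 120)
Kruskal-Wallis H = 269.0, p = 5.18e-58
strongA vs weak: Mann-Whitney U = 14320, p = 5.17e-40
```

Reading: estimated per-pair indel frequencies track the generator's ground
truth (Pearson r ≥ 0.95, mean absolute error ≤ 0.02 at depth 600), two
simulated biological replicates of the same effector agree at r = 0.987,
and the four effector models separate cleanly into the high/low activity
categories with the weak orthologue rejected by both nonparametric tests.

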