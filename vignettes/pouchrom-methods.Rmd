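---
title: "Methods: occupancy trajectories, chromatin opening and the synthetic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy trajectories, chromatin opening and the synthetic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and scientific background

`pouchrom` packages the integrative chromatin analysis used to dissect how
POU-family transcription factors reprogram somatic cells: Oct4 (the
canonical reprogramming factor, which heterodimerizes with Sox2 on
composite SoxOct DNA elements), Oct6 (a neural POU factor that instead
homodimerizes on the palindromic MORE element, ATGCATATGCAT) and an Oct4
point mutant unable to heterodimerize with Sox2 ("Oct4defSox2"). The
package covers six analysis layers:

1. **Occupancy trajectories** — ChIP-seq summits from ordered conditions
   (e.g. reprogramming days 1, 5, 7) are merged when within 100 bp
   (single linkage) and every merged locus receives a binary code, digit
   *i* being 1 iff the locus carries a summit from condition *i*. Three
   conditions give at most $2^3-1 = 7$ groups, four give 15.
2. **Motif annotation** — consensus-derived position weight matrices for
   the octamer (ATGCAAAT), SoxOct, MORE, MORE+1 (1-bp spacer variant) and
   single Sox site are scanned over a 200 bp window centered on each locus;
   per-group motif-class fractions summarize trajectory composition.
3. **Accessibility tiers and chromatin trajectories** — loci are tiered by
   raw MEF ATAC fragment counts (low < 15, medium 15–30, high > 30), and
   the MEF/day-1 peak universe is split into PO (permanently open), OC
   (open to close) and CO (close to open).
4. **Opening attribution** — candidate loci are classified by Sox2/POU
   co-binding and their day/MEF accessibility ratios compared with
   unpaired Wilcoxon rank-sum tests, Holm-adjusted across the pairwise
   family.
5. **Motif-accessibility deviations** — a compact reimplementation of the
   chromVAR-style deviation: observed minus expected motif-set counts over
   expected, standardized against accessibility-matched background peak
   sets.
6. **STARR-seq consensus enhancers** — a merged-library peak is a
   consensus enhancer iff it also overlaps peaks from at least two of
   three biological replicates; activity profiles are depth-normalized
   STARR minus input coverage.

A first-class synthetic-data generator emulates the binding and opening
structure these analyses assume and carries a machine-readable truth
table, so every stage has a recovery test.

# Data model and conventions

Intervals are tibbles in BED convention: `start` 0-based inclusive, `end`
exclusive. Overlap means sharing at least one base (`bedtools intersect
-u` semantics); adjacent half-open intervals do not overlap. Bulk overlap
and counting run on GenomicRanges/IRanges behind this surface, with the
coordinate shift confined to a single internal converter. A merged locus
records the envelope of its member summits and a representative position,
the floor of the envelope midpoint — the source analyses do not state
which coordinate represents a merged locus, and the midpoint is symmetric
and reproducible. Even-width resizing places the anchor at
`start + width/2`; windows clipped at a chromosome start are extended
rightward so the output width is preserved.

# PWM scanning

Scanning scores every offset by log-odds against a uniform 0.25
background. Columns are floored at a pseudo-probability of $10^{-3}$ and
renormalized; `N` bases in the genome score 0, so N-runs can never reach a
stringent threshold. Non-palindromic motifs are scanned on both strands; a
motif whose reverse complement equals itself (MORE) is scanned on the plus
strand only, so a perfect palindrome is counted once rather than twice.
The default match threshold is 85% of each PWM's maximum attainable score,
with consensus bases at probability 0.85. These two defaults make only
(near-)exact consensus matches score above threshold, which keeps the
empirical false-positive rate per 200 bp window below 5% for every class —
`measure_fp_rate()` reports about 0.7% for the octamer, about 2% for the
7-bp single Sox site and effectively 0 for the longer composite elements
on 10,000 uniform random windows. The canonical SoxOct and MORE+1
matrices are not published as consensus strings; the package ships
CATTGTTATGCAAAT and ATGCATNATGCAT as configurable placeholders, and any
MEME-minimal or tab-matrix PWM can be substituted via `read_pwms()`.
Fractions computed on real data will shift with the PWM and threshold
choice; the threshold is deliberately a visible knob.

# Normalizations and statistics

Two normalizations are kept strictly separate, mirroring how the
underlying assays are usually treated. ATAC-seq signal is
fragments-per-kbp-per-million (FPKPM): `count / (length/1000) /
(library_size/1e6)`. POU ChIP-seq count matrices, whose library sizes
differ too much for depth scaling, get a pseudo-count of 1 followed by
classic quantile normalization (rank each column, replace by the mean of
column-sorted values at that rank; tied values receive the mean of the
reference values over their rank range). The implementation is
cross-checked in the test suite against an independently coded
sort-and-average oracle and against `limma::normalizeQuantiles`.

Accessibility ratios are `(day + eps) / (mef + eps)` with `eps = 0.1` by
default: the source analyses do not state their zero handling, and the
epsilon bounds ratios at zero-MEF loci while preserving ordering; it is
exposed in every ratio-computing function.

Rank-sum comparisons use the Mann–Whitney U with midrank ties, exact by
enumeration when $n_x + n_y \le 12$ without ties and a
continuity-corrected normal approximation otherwise (`stats::wilcox.test`
provides both paths; the exact path is verified against full enumeration
of rank assignments). Fully tied samples carry no evidence and report
p = 1. The Holm family is all pairwise class comparisons within one
analysis, matching `pairwise.wilcox.test`. Note the normal approximation
can deviate from the exact p by up to a few hundredths at $n = 6 + 6$, so
no claim tighter than 0.02 is made for it.

The deviation score for motif set $m$ in sample $s$ uses
$E(m,s) = \sum_{p \in m} T_p \cdot N_s / N_{tot}$ (peak totals times the
sample's share of the grand total), raw deviation $(X - E)/E$, and a z
standardized over at least 50 background sets sampled within 10
accessibility bins matched to the motif set's per-peak mean counts. GC
matching is optional and off by default: the bias the correction targets
in this pipeline is count-depth, and full GC matching needs a genome
sequence.

# The synthetic generator

The generator is the package's study-conditions-in-code and is itself
tested, not a throwaway fixture.

* **Genome**: i.i.d. uniform background bases with exact consensus motif
  instances planted non-overlapping, at least 500 bp apart (so a 200 bp
  scan window sees at most one instance), positions, classes and strands
  recorded. Identical (config, seed) pairs are byte-identical, FASTA
  included.
* **Binding**: per (factor, day, motif-class) Bernoulli occupancy. The
  default rules encode the dimerization biology: Oct4 binds SoxOct at
  probability 0.85–0.9 on both days; Oct4defSox2 binds SoxOct at 0.8 on
  day 1 but 0.02 by day 5 with residual MORE binding (0.3); Oct6 binds
  MORE at 0.85 on both days and SoxOct at only 0.1; Sox2 binds single Sox
  sites at 0.7 and co-binds SoxOct loci only when the POU partner is both
  bound and heterodimerization-competent. Bound loci emit a summit at the
  motif center with ±20 bp uniform jitter.
* **Accessibility**: $P(\text{open}) = \mathrm{logit}^{-1}(\beta_0 +
  \beta_S S + \beta_O O + \beta_{OS} S O)$ with defaults $\beta_0 = -2$,
  $\beta_S = 2$, $\beta_O = 0.5$, $\beta_{OS} = 1$ — Sox2 the dominant
  opener, the POU factor an augmenter. In MEF no factor is present, so
  both indicators are 0 and opening occurs at the baseline rate
  $\mathrm{logit}^{-1}(-2) \approx 0.12$ (reading "no binding terms"
  literally; a strictly all-closed MEF would leave the permanently-open
  class empty and contradicts the baseline term). Open loci emit
  negative-binomial counts with mean 40, closed with mean 5, dispersion
  0.3 — chosen so the 15/30 tier thresholds split loci non-trivially —
  and counts materialize as 100 bp fragments uniform within the 500 bp
  locus window. ATAC peaks are windows with counts of at least 15,
  aligning the caller with the low-tier boundary.
* **STARR**: true enhancers (the loci open in the Oct4 day-1 condition)
  are called per replicate with sensitivity 0.8 and in the merged set with
  the pooled probability $1-(1-s)^3$; false positives are injected at 5%
  of the enhancer count away from the true set.

What the generator deliberately does not emulate: linked or clustered
enhancers (loci are independent), background fragments outside locus
windows, GC or PCR bias, nucleosome positioning, graded (non-two-state)
accessibility, and read-level sequence. Passing recovery tests therefore
demonstrate the correctness and calibration of the analysis logic under
the stated model — not performance on real libraries, where thresholds
and PWM choices dominate.

# Design choices in the attribution analysis

One choice deserves emphasis. Under the two-state emission model,
conditioning the co-binding comparison on loci that already carry a day-1
ATAC peak (the strict close-to-open set) makes the classes statistically
exchangeable: every such locus is open, and an open locus's counts do not
depend on which factor opened it. The biological signal — Sox2-bound loci
open more often than POU-only loci — lives in *whether* MEF-closed loci
open. `run_opening()` therefore takes an optional `universe` of candidate
loci (typically the day-1 bound regions); when supplied, attribution runs
over universe loci closed in MEF without conditioning on the day-1 peak.
With the default scenario this yields median day/MEF ratios ordered
shared > Sox2-only > POU-only with Holm-adjusted p-values far below 0.05,
and the peak-based PO/OC/CO classification remains available unchanged.

Orchestration is exposed as R functions (`run_simulate()`,
`run_trajectories()`, `run_opening()`, `run_starr()`), each optionally
writing its tables, per-code BEDs, a config-echoing run log and an
md5-checksummed manifest into a run directory; an R API rather than a
shell entry point because the package's users drive these analyses from
R, and the functions compose.

# Problem sizes and reproducibility

The shipped tests and the acceptance script use: 3000 planted loci (900
SoxOct, 700 MORE, 500 octamer, 300 MORE+1, 600 single Sox) on a 3 Mb
two-chromosome genome; 100 seeds × 3000 loci for opening-model
coefficient recovery (each coefficient recovered within ±0.3,
$\hat\beta_S > \hat\beta_O$ in ≥95% of seeds); 10,000 random windows for
the false-positive-rate report; and 20 random instances per oracle
equivalence (summit merging vs connected components, scanning vs
brute-force scoring, exact rank-sum vs enumeration, quantile
normalization vs sort-and-average). Every stochastic step takes an
explicit seed and the generator guarantees byte-identical reruns.

# Known limitations

* Motif fractions on real data depend on the PWM database and per-motif
  thresholds; the shipped consensus PWMs are placeholders for two classes.
* The deviation score implements the core statistic only — no
  variability, synergy or embedding features.
* Exact rank-sum p-values with ties are out of scope (midranks + normal
  approximation are used instead).
* Tier counts use raw fragment counts over the peak interval itself;
  whether the original tiering counted over the peak or a fixed summit
  window is unstated, and tier sizes are sensitive to that choice.
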