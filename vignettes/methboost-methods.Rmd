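---
title: "Predicting CpG methylation states across sparse single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CpG methylation states across sparse single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methboost)
```

## The problem

Single-cell bisulfite protocols (scBS-seq, scRRBS) observe only a small
fraction of a cell's CpG sites — typically 20–40% for scBS-seq and 1–10% for
scRRBS — and each observed site carries only a handful of reads. Most
downstream analyses need complete binary methylation maps, so the missing
states must be predicted. Two structural facts make this tractable:
methylation is strongly spatially correlated along the chromosome, and cells
profiled together share much of their methylation landscape, so a site
unobserved in one cell is often observed in another.

`methboost` predicts the binary state of a CpG site in a target cell from
three feature families, concatenated into one matrix and fed to a
gradient-boosted tree classifier trained per target cell:

1. **Sequence** (84 features): frequencies of all 1-, 2- and 3-mers over
   `{A,C,G,T}` in the 101-bp window centred on the site's cytosine. For an
   n-mer *v*, the feature is `N(v) / (L - (n - 1))` — the count of
   overlapping occurrences divided by the number of length-n windows.
2. **Structural** (175 features with the conventional manifest): binary
   overlap of the site with annotation tracks — CpG islands, shores,
   shelves, 144 TFBS tracks, 15 chromatin states, 10 histone marks, DHS —
   plus two per-position scores (iHS and evolutionary constraint).
3. **Positional** (`4m + 8(m-1)` features for m cells, e.g. 292 for
   m = 25): for every cell *j*, the signed distances and states of the
   labeled sites flanking the target position in *j* (4 values; the
   target's own state is excluded even for *j = i*); and for every *other*
   cell *j ≠ i*, the consecutive inter-site gaps and endpoint states around
   the target position in *j* (8 values). The same-cell 8-value block would
   contain the target's own label and is therefore forbidden.

## Labels

States come from read counts by majority: methylated if more than half the
reads at a site are methylated, unmethylated if fewer. Sites with fewer than
4 total reads are excluded (coverage filter, the conventional threshold,
exposed as `min_cov`), and exact 50/50 ties are excluded too: a site that is
neither mostly methylated nor mostly unmethylated has no usable binary
label. Models are trained and evaluated under chromosome hold-out: odd
autosomes 1–11 train, even autosomes 2–12 test, 13–19 validate (the split is
a `split_spec` and fully configurable).

## Positional feature conventions

Several conventions are deliberate and worth stating:

* **Distances are raw signed base-pair offsets** (upstream negative). No
  normalisation is applied because the feature definitions use raw
  distances and boosted trees are invariant to monotone rescaling anyway.
* **Missing neighbours are `NA`**, not sentinels: chromosome boundaries,
  cells with no labeled site on a side, and out-of-range indices all encode
  as missing. Boosted trees route missing values natively; a numeric
  sentinel would distort split selection.
* **The duplicated middle gap** in the 8-value block when the target
  position is absent from the other cell is kept verbatim (the block is the
  union of two 4-value halves that share the spanning gap); this keeps the
  block width constant at 8. Dropping the duplicate would only remove a
  redundant column, which trees ignore at no cost.
* **Cell order is fixed**: lexicographic cell id, target cell's flank block
  first. Models therefore transfer across runs and processes.
* **"k-th distance" means neighbour rank**: the k-th nearest labeled site
  on each side, never the k-th base pair. The production feature set uses
  rank 1 on both sides (`k1 = k2 = 1`), the setting the skip-k analyses
  below justify; larger windows are available through `skip_k_features()`
  for those analyses only.

## The classifier

Training is delegated to xgboost's histogram-based booster with leaf-wise
growth (`tree_method = "hist"`, `grow_policy = "lossguide"`), the same
algorithmic family as the GOSS/EFB-style boosters used for large sparse
feature sets. Defaults: 110 trees, maximum depth 5, 22 leaves, learning
rate 0.04. `threads = 1` by default: single-threaded histogram training is
bit-reproducible under a fixed seed, and the package's determinism
guarantees are stated at that setting; raise it for speed when
reproducibility across thread counts is not needed.

`goss_select()`, `efb_conflict()`, `efb_bundle()` and `merge_bundles()` are
reference implementations of gradient-based one-side sampling and exclusive
feature bundling, provided for study and experimentation with their own
tests; they are not wired into the delegated trainer, whose internal
sampling and bundling are behaviourally equivalent. Two design points:

* **GOSS weighting.** The remainder sample is up-weighted by its inverse
  sampling fraction `r / ceil(b·r)` (~`1/b`, the Horvitz–Thompson weight
  under "b is a fraction of the remainder" semantics), which preserves the
  expected total gradient mass exactly — the property the amplification
  exists to provide. `a`, `b` have no canonical published values; defaults
  are `a = 0.2`, `b = 0.1`, both exposed.
* **Bundling.** A feature joins the first existing set whose total added
  conflict is `≤ d` (the inclusive comparison makes `d = 0` mean "merge
  only provably exclusive features", which is the natural reading of a zero
  budget). Merging uses a mixed-radix generalisation of the histogram
  offset construction over non-negative integer-valued (binned) columns:
  every feature occupies its own digit, zero stays the shared zero bin, and
  the original columns are exactly recoverable for *any* plan — simple
  additive offsets would lose information whenever a tolerated conflict
  actually occurs. `d` defaults to 0.05, exposed.

## Evaluation

Eight measures: accuracy, precision, sensitivity, specificity, F-score,
MCC, AUC and AUPR. Any thresholded metric with a zero denominator is
reported as 0 and the affected names are listed in the report's
`degenerate` field, so the convention is never silent. AUC is trapezoidal
over the score-grouped threshold set (equal to the Mann–Whitney statistic
with half-credit for ties); AUPR is step-integrated (each recall increment
contributes the precision at that threshold). AUPR is reported because
methylation labels are routinely imbalanced and the PR curve is more
sensitive to the minority class than the ROC.

## The simulator

Every stage is testable offline against `simulate_study()`, which emulates
the regime of sparse single-cell methylomes:

* a random genome with CG dinucleotides planted at geometric gaps (mean
  100 bp, roughly genome-wide CpG density) and accidental background CGs
  removed, so the planted positions are exactly the CpG sites;
* a latent binary methylation landscape per chromosome — a symmetric
  two-state Markov chain in genomic distance with per-bp switch rate
  `q = 1e-3`, giving state-flip probability `(1 - (1-2q)^g)/2` over a gap
  of g bp and a correlation length of ~500 bp (this saturates at 1/2 for
  large gaps, as a two-state chain must);
* per-cell deviation from the latent landscape with concordance 0.9 —
  the partial cross-cell agreement that makes other-cell features
  informative but imperfect, mirroring the overlap statistics observed in
  real multi-cell datasets;
* observation of each (cell, site) pair with probability 0.3 (scBS-seq-like
  sparsity), depths `1 + Poisson(9)` so the ≥4-read filter genuinely
  excludes a fraction of sites, and a 5% per-read error rate;
* 175 annotation tracks, with CpG-island intervals preferentially placed
  over unmethylated latent runs (CGIs are hypomethylated in real genomes;
  the `enrichment` knob tunes or disables this association) and the
  remaining tracks placed independently.

Defaults are 5 cells and 2 chromosomes of 1 Mb — about 10,000 CpG sites per
chromosome, ~3,000 observed per cell per chromosome — sized so the full
pipeline (simulate, extract 311 features, train, evaluate, three feature
families, three seeds) runs in well under a minute per seed on one CPU.

What the simulator does **not** emulate: real sequence composition. The
background is uniform random, so sequence features carry essentially no
signal here (held-out AUC ≈ 0.5), whereas on real genomes sequence
composition is genuinely predictive. Consequently the simulator supports
*ordering* claims (all features ≥ sequence+structural ≥ sequence; nearest
neighbours beat distant ones) and machinery correctness, not the absolute
AUC levels reported on real data. It also does not simulate bisulfite reads
at the sequence level, strand effects, copy-number variation, or cell-type
mixtures.

## Numerical and degenerate-input choices

* Sequence windows at chromosome ends are N-padded to full width; n-mer
  windows containing N count toward no feature while the denominator stays
  nominal, keeping feature scale constant across sites. (How ambiguous
  bases should be handled is not standardised; this choice is ours.)
* BED input is 0-based half-open and converted to 1-based closed
  coordinates once, at load time. Profile TSVs are 1-based.
* Missing annotation scores are `NA`, not 0 — zero is a meaningful score
  value for iHS/constraint.
* Shores are the ±2 kb flanks of CpG islands and shelves the next 2 kb
  out, with inner territory subtracted so the three classes are disjoint —
  the conventional widths, used when deriving tracks for fixtures.
* Cross-cell overlap statistics count (cell, site) records: `N1` records at
  positions known in ≥2 cells, `N2` records whose own state is shared by
  ≥1 other cell at the position. The "all cells known and unanimous" rule
  used for `N3` is one reading of an ambiguous published definition; the
  predicate is a replaceable function argument.
* Empty partitions, single-class labels, i = j gap blocks, and mismatched
  prediction manifests are errors, never silent degradation.

## Reproducibility

Every stochastic component takes a seed: the simulator derives separate
streams per stage from its master seed (identical seeds give byte-identical
FASTA/TSV/BED output), and training is deterministic given a seed and one
thread. The test suite verifies hash-identity of a full
simulate→extract→train→predict run repeated under one seed.
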