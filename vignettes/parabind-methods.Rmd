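---
title: "Models and methods behind parabind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind parabind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parabind)
```

`parabind` analyses how two paralogous transcription factors — the
motivating case is a pair of Fos-family AP-1 subunits binding TRE-like
`TGAC/GTCA` motifs — divide a genome between them. This vignette
explains each model, its assumptions, the tunable parameters, and the
design decisions taken where more than one reasonable choice existed.

## Coordinates and containers

All genomic intervals are tibbles in the BED dialect: 0-based,
half-open `[start, end)`. Inputs in 1-based conventions must be
converted at the reader boundary; using a single convention everywhere
removes off-by-one drift between modules. Interval algebra
(intersection, gap-merging, subtraction) is delegated to IRanges behind
the tibble surface; the test suite verifies every operation against
independent per-base brute-force oracles, so the delegation is checked,
not trusted.

## Threshold peak calling

`call_peaks()` reproduces genome-browser-style thresholding: a peak is
a maximal run of bases whose signal is at least the threshold, with an
optional minimum length (default 1 base and no gap-joining — the
simplest reading of a thresholding screenshot rule). The peak score is
the maximum signal inside the peak, and the summit is the *leftmost*
base attaining that maximum (an explicit tie-break so downstream
window-centring is deterministic). Bases not covered by any bedGraph
step count as zero signal. The conventional threshold for the
ChIP-seq-like tracks in the demo is 50 signal units.

## Site classification

`classify_overlap()` unifies every transitively overlapping group of
peaks from the two factors (at least one shared base; merely touching
peaks stay separate) into one record spanning the union, labelled
`F1F2`; factor-exclusive peaks become `PF1` or `PF2`. One record per
binding site matches how shared sites are displayed as single heatmap
rows. When signal tracks are supplied, both factors' signals are
recorded at every classified site, so sub-threshold signal at
preferential sites remains inspectable; the classification itself uses
only the called peak sets.

## Chromatin-state rules

`annotate_elements()` applies fixed rules, in decreasing precedence:

* promoter domains are symmetric TSS ± 1,500 bp windows ("centred on"
  the TSS, hence strand-independent); overlapping domains from close
  TSSs are unified so states stay base-disjoint;
* a promoter domain overlapping an H3K27ac peak is a candidate active
  promoter (`cAP`), otherwise candidate inactive (`cIP`);
* H3K4me1 peaks with all promoter-domain bases subtracted are enhancer
  candidates; pieces overlapping H3K27ac are `cAE`, the rest `cIE`.

"Low H3K27ac content" for `cIE` is operationalised as *no overlap with
a called H3K27ac peak* — no quantitative bound exists for it, and the
binary rule keeps states checkable against a per-base oracle. H3K4me3
is carried as a reported annotation layer only; it does not enter the
state rules.

## Motif model

A PWM is a per-position base-probability matrix. A window's raw score
is its summed log2 odds against the background (uniform by default);
`N` bases contribute zero. The **score ratio** normalises the raw score
by the PWM's best and worst attainable windows:

$$\mathrm{ratio} = \frac{\mathrm{raw} - \mathrm{min}}{\mathrm{max} - \mathrm{min}} \in [0, 1],$$

the scale on which the occurrence threshold 0.80 is expressed. A
degenerate PWM whose best and worst windows tie gets ratio 1 by
convention. Scanning covers both strands (minus-strand windows score
the reverse complement, implemented by scanning with the
reverse-complemented PWM); the occurrence threshold is a strict `>`,
except at `min_ratio = 1` where the comparison is inclusive so
perfect-score windows remain reportable. Occurrence *counting*
collapses plus/minus hits at the identical span to one site, keeping
the higher-scoring strand — AP-1-like motifs are near-palindromic and
would otherwise be double-counted. Counts-to-probabilities conversion
uses `(count + pc) / (n + 4 pc)` with a default pseudocount of 0.01
for JASPAR matrices and 0 for reconstruction.

Per-column information content under uniform background is
`2 + sum_b p(b) log2 p(b)` bits, from 0 (no preference) to 2 (single
base); reconstructed-motif comparisons use the column total. The inner
window-scoring loop is compiled (Rcpp) because the feature-matrix build
scans hundreds of PWMs over 1,001-bp windows.

## Binding-preference discrimination

`build_feature_matrix()` summarises each peak as the 1,001-bp sequence
centred on its summit, with one feature per library PWM (the maximum
score ratio over all windows and strands) plus 12 composition features:
mononucleotide classes `A+T` and `C+G`, and the 16 dinucleotides
collapsed by reverse-complement equivalence into 10 strand-symmetric
classes. A 550-PWM library therefore yields 662 features.

`fit_classifier()` / `fit_ratio_regressor()` implement one protocol:
classes are balanced by seeded downsampling; rows are split 70/30 with
stratification (by class, or by response quartile for regression);
features are standardised to zero mean and unit variance *on the
training rows only* (L1 selection is scale-sensitive, and PWM ratios
and composition rates live on different scales); an L1-penalised model
is fit with `glmnet::cv.glmnet` over 100 log-spaced penalties from the
data-derived `lambda_max` down to `lambda_max * 1e-4`, with 10-fold
cross-validation folds drawn only from the training split (preventing
leakage into the reported test metric; whether the original protocol
did this is unknowable from the description, so the safe variant was
chosen); the selected penalty is `lambda.min`. Held-out evaluation is
the midrank AUC (classification; positive coefficients point toward
the configured positive class, `PF1` by default, and flipping the
encoding flips all signs) or the Pearson correlation between predicted
and observed log-ratios with its p-value (regression).
`single_feature_auc()` ranks the same held-out rows by one raw feature,
with the ranking direction chosen on the training rows, measuring how
far a single motif goes relative to the full model.

## Regulation groups

`classify_genes()` maps per-gene modulation calls under conditions
`si1`, `si2` (single knockdowns) and `si12` (double) to:
**A** (si1 modulates, si2 does not — si12 is deliberately ignored, as
the double knockdown may merely strengthen the single effect),
**B** (symmetric), **C** (only the double modulates — redundancy),
**D** (both singles modulate in the same direction *and* the double
effect is strictly stronger, `|fc12| > max(|fc1|, |fc2|)` —
complementarity). Genes where both singles modulate but the strength
test fails are assigned `none` with a `both_nonadditive` flag;
discordant single directions get a `discordant` flag. Flagging rather
than silently assigning keeps the A–D partition faithful to its
definitions while losing no genes. Fold changes use the signed-ratio
convention (magnitude always ≥ 1) and the |FC| ≥ 1.5 filter is
inclusive at the boundary.

## Capture-C interaction calling

A viewpoint profile holds per-restriction-fragment unique-interaction
counts for one captured promoter, per replicate.
`normalize_profile()` scales each replicate so its total count outside
the viewpoint exclusion zone (default 2 fragments each side, where
undigested and self-ligation artefacts concentrate) equals the
replicate-mean total — a minimal depth normalisation that preserves
within-replicate ratios. `background_fit()` fits, independently per
side of the viewpoint, a non-increasing isotonic regression of the
replicate-mean count on distance: a distribution-free stand-in for a
parametric distance-decay model that needs no functional-form
assumption. The fit is made robust by a second pass: fragments whose
first-pass residual exceeds 3 median absolute deviations — candidate
interactions — are masked, the isotonic fit is recomputed without
them, and their expected values are interpolated from the refit.
Without this, strong interactions inflate the very background they are
tested against, truncating the edges of recovered regions. Sides with
fewer than 20 fragments are skipped.

`call_pirs()` then tests for spatially coherent enrichment: fragment
residuals (observed mean − expected) are smoothed with a centred
`w_size = 5` fragment window; an empirical null is built from seeded
random permutations of the residual vector; one-sided permutation
p-values (with the add-one correction, which is conservative) are
Benjamini–Hochberg adjusted at `alpha_fdr = 0.1`; a fragment is called
only if additionally its count is at least `q_wr = 1` times the
expected background in *every* replicate (the per-replicate
consistency reading of the ratio-multiplier parameter); adjacent
called fragments merge into one region. Permuting rather than
circularly shifting the residual vector is deliberate: a shift
preserves the planted enrichment run intact inside every null vector,
so the null tail always contains the signal windows themselves and the
test can never reach significance against strong signals — shuffling
keeps the marginal residual distribution, which is the correct null
for "no spatial coherence". PIR distances are measured viewpoint
midpoint to region midpoint.

## The synthetic generator

Every generator is a pure function of a single seeded configuration
(`sim_config()`), and each emits a truth table alongside its data, so
downstream tests consume truth instead of re-deriving it. Defaults are
the package's study conditions:

* genome: i.i.d. sequence at GC 0.5; TSSs on a spacing-respecting grid;
* motifs: a 7-column strict PWM (0.91 on the `TGACTCA` consensus base
  per column, high information content) and a degenerate PWM of the
  same length (0.55 consensus probability, two near-uniform end
  positions) — chosen so that the strict motif alone discriminates the
  planted classes at roughly the qualitative level seen in real
  ChIP-seq discrimination tasks, without tuning to any particular
  number;
* planted sites: `PF2`-truth sites draw from the strict PWM; `PF1`
  sites from the degenerate PWM with flanking bases within ±500 bp
  resampled toward A/T to produce a +0.10 AT excess (at background
  AT 0.5); shared `F1F2` sites draw from strict/degenerate mixtures
  with planted signal log-ratio `−β·(strict ratio − 0.5) + noise`
  (β = 1, Gaussian noise sd 0.15), clamped to ±0.4 with base heights
  ≥ 100 so both factors' rectangular signal peaks (heights 80–200 over
  a ≤ 10-unit noise background) stay above the calling threshold of
  50 — the high-signal-to-noise regime in which planted classes are
  recoverable end to end;
* histone landscape: marks placed per element class with configurable
  dropout; open-chromatin placement probabilities per class (0.733 for
  cAE, 0.886 for cAP, 0.254 for cIE, 0.134 for cIP) emulate the
  typical open-chromatin enrichment of active elements;
* capture: pseudo-digested fragments (mean 400 bp, minimum 80),
  negative-binomial counts (dispersion 0.3) with mean
  `A/(1 + d/d₀)` (A = 120, d₀ = 50 kb), planted interacting regions as
  4× multipliers over 5-fragment runs, three i.i.d. replicates;
* expression: truth groups at configured proportions with fold-change
  magnitudes in [1.6, 4]; for group D the double-knockdown magnitude is
  1.2–1.8× the stronger single. An optional error rate flips
  modulation booleans independently.

What the generator does *not* emulate: read-level artefacts
(mappability, GC bias, duplicates), motif co-occurrence structure,
correlated replicates, and real distance-decay heterogeneity. Passing
tests on this generator therefore demonstrate correctness of the
*procedures* under their stated assumptions, not performance on real
libraries.

## Problem sizes and numerical choices

The test suite runs the oracle-equivalence checks on ~1,000 randomized
small genomes (≤ 10 kb), the discrimination-recovery study on 20 seeded
replicates of 2 × 1,000 balanced peaks over 3.2-Mb genomes, the
regression study at 2,000 shared sites, and the interaction-caller
study on 50 null plus 50 planted viewpoints of 400 fragments each —
sizes at which every property is measurable in minutes on a laptop
while leaving no stage untested. The discrimination-recovery study
turns the AT-flank boost off so that motif stringency is the single
planted discriminating feature; with the boost on, the composition
features separate the classes nearly perfectly and the comparison
between the full model and the single strict-motif feature becomes
uninformative. Under the stringency-only conditions the full-model AUC
sits by construction near 0.75, so that recovery property is assessed
as a mean over the 20 replicates rather than on a single draw.

Other numerical conventions: degenerate score ranges fall back to
ratio 1; permutation p-values use the add-one correction; AUC uses
midranks for ties; isotonic fits are clipped at zero; all randomness
flows from user-supplied integer seeds and nothing is cached between
stages.

## Known limitations

The PIR caller is a defined simplification, not a reimplementation of
any published caller: its three parameters keep their published
meanings, but absolute sensitivity/specificity are not comparable to
other tools. The chromatin-state rules are binary overlap rules, not a
hidden-Markov segmentation. The discrimination module models marginal
motif preferences only — no pairwise motif-interaction terms. Real-data
headline numbers from the motivating study (classification AUC ≈ 0.8,
shared-site ratio correlation ≈ 0.3, PIR counts and distances) depend
on the original sequencing data and serve as qualitative patterns for
the synthetic studies, not as numeric targets.
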