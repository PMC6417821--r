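---
title: "Latent epigenomic factors from ChIP-seq peak maps: models and methods"
author: "ChIPLatent authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent epigenomic factors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChIPLatent)
```

# Overview

`ChIPLatent` turns a heterogeneous compendium of ChIP-seq peak calls into a
queryable latent representation of the regulatory genome. The pipeline has
five stages — featurization, batch normalization with signal protection,
SVD factorization with interpretable scores, functional annotation through
GREAT, and locus queries — and this vignette documents the model behind
each stage, the tunable parameters with their defaults and units, the
numerical conventions, and the design decisions taken where the procedure
was genuinely open.

# Featurization: the ChIP-map

Each track is a peak file whose score column is a −log₁₀ FDR q-value
(dimensionless, ≥ 0; in a corpus called at q ≤ 10⁻⁵ every real score is
≥ 5). Autosomes are tiled into fixed bins (`binSize`, default 1,000 bp,
BED convention: 0-based, half-open). Each peak contributes its score to
every bin it overlaps by at least 1 bp — plain BED-intersect semantics,
deliberately not length-weighted, so a peak spanning two bins contributes
its full score to both. Scores of one track landing in one bin are
**summed** by default: summing accumulates evidence when several peaks of
one assay hit the same kilobase, which is the behaviour we want for a
significance-weighted feature. Because the choice is not forced by the
model, `aggregate = "max"` is available.

Two reference flavours trade specificity against coverage: the
high-specificity map keeps the `nTop` = 25,000 strongest peaks per track
(reducing experimental-design confounding); the high-coverage map keeps
everything. Ties at the cutoff are broken by (chromosome, start), making
the filter deterministic. Bins never hit by a peak are removed — the
reference therefore does not cover the whole genome, and query loci in
uncovered regions are reported as unmapped rather than scored. Empty
tracks are dropped before assembly. A trailing partial bin per chromosome
is emitted; on real chromosomes with 1 kbp bins this changes at most one
bin per chromosome and avoids silently truncating the tail.

# Batch normalization with covariate-protected surrogate variables

Corpora aggregated from public databases mix laboratories, protocols and
populations, and their metadata are heavily incomplete. The normalization
stage therefore works unsupervised first and consults metadata second:

1. **Transform.** `log(score + pseudocount)` with `pseudocount` = 1 (scores
   are ≥ 0, and 1 keeps zero at zero), then per-bin centering, then
   per-bin scaling to unit standard deviation. The log comes first because
   centering produces negatives. Bins with zero variance after the log
   carry no information and are dropped with a diagnostic count.
2. **SV estimation.** Surrogate variables are the left singular vectors of
   the transformed matrix whose singular values exceed the
   (1 − `sigLevel`) quantile of the corresponding singular values under
   `nPermutations` independent column-wise permutations (parallel
   analysis, Buja–Eyuboglu). Permuting each bin column independently
   preserves every marginal distribution while destroying cross-track
   covariance, so retained components carry variation shared across rows
   and columns at a rate greater than chance. Defaults: 100 permutations,
   `sigLevel` 0.05, explicit `seed` (default 1). This is a deliberately
   transparent member of the SVA family: it is not the iteratively
   reweighted algorithm of the reference implementation (empirical-Bayes
   shrinkage and iterative reweighting are out of scope), and a test
   cross-checks that on a planted-batch fixture both estimators recover
   the same direction.
3. **Labelling.** Each SV is regressed on each covariate over the tracks
   with that covariate observed (categorical covariates one-hot encoded;
   the overall F-test p-value is recorded — for a continuous covariate
   this equals the slope t-test). An SV is labelled with every covariate
   whose p-value falls below `alphaAssoc`. Covariates with fewer than
   three observed tracks, a single observed level, or no residual degrees
   of freedom are skipped with a diagnostic. The default
   `alphaAssoc` = 10⁻³⁰ is calibrated to corpus-scale cohorts (hundreds of
   tracks), where a genuine antibody association is numerically
   indistinguishable from zero. The attainable p-value floor scales with
   the cohort: with ~20 tracks a *perfect* association only reaches
   p ≈ 10⁻²⁰–10⁻³⁰, so desk-scale analyses in this package (tests,
   acceptance script) use `alphaAssoc` = 10⁻¹⁰. The threshold is a
   labelling sensitivity, not a multiple-testing correction.
4. **Protected regression.** SVs labelled with any covariate in
   `protectedCovariates` (typically `antibody` — the biological axis of a
   ChIP-seq corpus) are excluded from the regressor set. The remaining SVs
   plus an intercept form one design matrix whose QR factorization is
   applied simultaneously to all bins; the residual matrix `W` is exactly
   orthogonal to every removed SV. Regressing twice changes nothing
   (idempotence), and if everything is protected the input is returned
   with a warning.

One caveat is inherited from the two-step design: **unlabelled SVs are
removed**. When metadata are missing for a biologically relevant covariate,
its variation cannot be labelled, hence cannot be protected, and will be
regressed out. We keep this behaviour (it is the conservative reading of
"remove everything you cannot attribute to protected biology") and flag it
here rather than guessing a heuristic.

# Latent factors and their scores

The thin SVD `W = U D Vᵀ` (K = min(N, M) by default; truncation only on
request) yields track singular vectors `U`, non-increasing singular values
`D`, and bin singular vectors `V`. Signs are fixed so the
largest-magnitude entry of each `V` column is positive — scores are
invariant to simultaneous sign flips, and the convention makes pipelines
reproducible across linear-algebra backends.

With bin factor scores `G = V D` and sample factor scores `S = U D`:

* bin contribution `cntr_k(j) = v_{j,k}²` — the share of factor *k*
  carried by bin *j*; sums to one over bins by orthonormality of `V`. The
  identity is asserted in the test suite rather than re-normalized at run
  time.
* bin squared cosine `cos²_j(k) = g_{j,k}² / Σ_{k'} g_{j,k'}²` — the share
  of bin *j*'s identity explained by factor *k*; sums to one over factors.
  A bin with an all-zero score row (possible only in degenerate inputs) is
  an error naming the bin.
* sample contribution and sample squared cosine, the same constructions on
  `S`; contribution columns of zero singular values are undefined and
  reported as excluded factors.

Variance explained per factor is `d_k² / Σ d²` with cumulative sums.

# Functional annotation

For each factor the top `nBins` = 5,000 bins by contribution (ties by
genome order) are exported as a sorted BED3 query. The GREAT web service
is **not** called — builds stay hermetic and offline; instead its exported
result tables are parsed back (header-driven, with a column-alias map
covering the export dialects), keeping the binomial-test statistics:
binomial p-value, binomial FDR q-value and fold enrichment. Terms are
ranked ascending by binomial FDR with ties broken by p-value then term id
(a total order, so annotation is reproducible), and an optional FDR
ceiling filters the list.

# The query pipeline

SNP positions are 1-based on input (GWAS-catalog convention) and converted
internally; intervals may be given in BED coordinates. A SNP maps to the
unique reference bin containing it; an interval maps to every overlapping
bin; loci over removed (peak-free) bins are returned as unmapped, never
silently dropped. Factors are ranked by the weighted average of bin
squared cosines over the mapped bin set, a convex combination that again
sums to one. Weights default to uniform per locus; when several loci land
in one bin their weights are **summed** into that bin, so a doubly-hit bin
counts twice under uniform weighting — the average is defined over bins,
and this choice preserves per-locus uniform weighting. The reference
flavour (high-specificity vs high-coverage) is an explicit choice at build
time with no default, because it is a real sensitivity/coverage trade-off
the analyst should own.

Two systematic analyses sit on top: a GWAS-catalog coverage table
(intergenic-classified SNPs excluded first — the pipeline targets
cis-regulatory variation — and percentages computed over the
post-filter denominators), and a rank-robustness analysis: rank factors
for a locus group jointly, take the top `nGroupFactors` (default 5), then
re-rank for each locus alone and report, per group factor, the cumulative
fraction of loci placing it within the top *n* ranks, against the uniform
null *n*/K. The group-level aggregation uses the same weighted
squared-cosine average as ordinary multi-locus queries — it is the one
multi-bin ranking the method defines.

# The synthetic corpus

`syntheticDesign()` encodes the statistical structure the pipeline assumes
in real corpora, at desk scale: 24 tracks over a 5,000-bin genome (two
autosomes, 1 kbp bins); a 4-level antibody covariate (6 tracks per level);
three planted biological factors whose track loadings are mutually
orthogonal ±1 contrasts over the antibody groups; one technical batch tied
to a 2-level ancestry covariate balanced within antibody groups (hence
orthogonal to all three contrasts); disjoint bin supports of 300/200/120
bins with peak-score amplitudes 8/6/4 above a base score of 20; Gaussian
score noise (sd 1); 20% of metadata cells blanked; and a score floor of 5
imitating the q ≤ 10⁻⁵ corpus threshold. Support sizes decrease with
amplitude so the factors' variance ordering matches the declared amplitude
ordering after per-bin scaling (scaling normalizes column variances, so
support size, not raw amplitude, dominates a factor's singular value — the
two orderings are kept aligned by construction). Orthogonality of the
planted loadings is a validity condition of the design class: it is what
makes recovery testable, because non-orthogonal group indicators would mix
in the singular vectors.

Everything is deterministic per seed (byte-identical files), truth tables
record every planted vector, and `generateQueryTruth()` emits SNPs in
known supports plus decoys in peak-free regions with their expected
outcomes. Peaks sit exactly on bin boundaries by default; `jitterPeaks`
shifts them across boundaries to exercise intersection edge cases.

What the generator deliberately does **not** emulate: linkage
disequilibrium between query SNPs, peak-width and peak-shape variation,
read-level count noise, overlapping or correlated biological programs,
non-autosomal contigs, and covariates confounded with biology. Passing
tests on this corpus therefore demonstrate the correctness of the
machinery (featurization, protection scheme, decomposition, scores,
query), not the biological fidelity of results on any real compendium —
on real data the signal-to-noise, the missingness pattern and the
non-orthogonality of real programs all bite, and the labelling threshold
in particular must be chosen for the cohort at hand.

The problem sizes used throughout the tests and the acceptance script
(24 × ~770 non-empty bins, 50 permutations, 50-seed score-identity sweeps
up to 50 × 500) were chosen so the full suite runs in well under a minute
while every planted effect is recovered with margin.

# Numerical choices and degenerate inputs

* Coordinates: BED 0-based half-open externally, `GRanges` 1-based closed
  internally; conversion happens exactly once at the I/O boundary.
* Overlap threshold ≥ 1 bp; strand ignored (peaks are unstranded);
  chromosome names normalized to the `chr` prefix on read.
* Text serialisation uses `%.17g`, so write/read round trips are
  bit-exact.
* Score identities are exact to ~10⁻¹⁰ in double precision; the QR
  residuals agree with normal-equation residuals to 10⁻⁸ (tested).
* Malformed BED lines reject the whole file with the line number; empty
  files are empty tracks (dropped); an all-empty corpus is an error at
  map assembly.
* Ties: top-peak filter and top-bin ranking break ties by (chromosome,
  start); factor ranking breaks score ties by factor index.

# Limitations

* The SV estimator is single-pass parallel analysis, not iteratively
  reweighted SVA; on corpora where the biology dominates variance the
  iterative scheme can separate signal from batch more finely.
* Removing unlabelled SVs can delete biology that has no metadata to
  protect it (see above).
* The reference covers only peak-bearing bins; coverage of query sets is
  structurally incomplete and should be reported alongside results (the
  coverage table does this).
* GREAT is consumed through files, so annotation freshness is the user's
  responsibility; the binomial model itself is not re-implemented.
* Randomized/streaming SVD for corpus-scale matrices is not included; the
  decomposition is dense and in-memory.
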