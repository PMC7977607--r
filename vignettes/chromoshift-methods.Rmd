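---
title: "Methods: comparative 3D-chromatin analysis with chromoshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative 3D-chromatin analysis with chromoshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoshift)
```

chromoshift compares the 3D chromatin architecture of a genome between
two conditions — typically a control and a stress treatment — from
binned Hi-C contact matrices, and integrates the architectural changes
with gene expression and chromatin accessibility. This vignette is the
package's own account of the models and the numerical choices behind
each step.

## A/B compartment calling

Compartments are called per chromosome from the observed/expected
(O/E) correlation structure of the contact matrix, usually at 100-kb
resolution:

1. The *expected* contact at bin separation $d$ is the mean raw count
   over all intra-chromosomal bin pairs at that separation (zeros
   included). O/E divides each observed count by this expectation;
   entries whose expectation is zero are treated as missing, not zero.
2. Bins with a zero raw marginal, or with more than half of their O/E
   row undefined, are masked (a standard low-coverage guard).
3. The Pearson correlation of every pair of unmasked O/E rows gives
   the correlation matrix; remaining pairwise-incomplete cells are set
   to zero before eigendecomposition.
4. PC1 is the leading eigenvector of that correlation matrix (not of a
   centered covariance, and not genome-wide), scaled by the square
   root of its eigenvalue.
5. The eigenvector sign is arbitrary, so PC1 is oriented per
   chromosome to correlate non-negatively with per-bin gene density:
   the A compartment is the gene-rich, active one. Positive PC1 bins
   are labeled A, negative B.

Centromeric bins receive no special handling beyond the coverage mask.

**Switch classification.** Given two profiles on the same grid, each
bin is classed A-A, B-B (stable), A-B or B-A (switching; condition-1
label first). Because eigenvector noise near zero would otherwise
manufacture switches, a bin is "no call" when its |PC1| falls below a
dead zone of $0.01 \times \mathrm{sd}(\mathrm{PC1})$ on that
chromosome. The dead-zone width is deliberately small: it suppresses
sign noise without eating real switches; recovery on synthetic data is
insensitive to values between 0.001 and 0.05. Contiguous bins of one
switching class are merged into segments, and both bin counts and
segment counts are reported, since "number of switching compartments"
can reasonably mean either.

## TAD calling

TADs are called at fine resolution (5 kb by default) with a
separation-score approach:

- **z-score matrix.** Counts are standardized per chromosome within
  each diagonal (distance stratum), using the population (n)
  standard deviation; a stratum with zero sd gets z = 0. Only
  separations up to twice the largest window are needed.
- **Separation score.** For each inter-bin boundary and window size
  $w$, the score is the mean z over the $w \times w$ "diamond" of bin
  pairs linking the $w$ bins upstream to the $w$ bins downstream. The
  final track averages the per-window scores with equal weight over
  windows of 15-30 kb in 5-kb steps. Strong boundaries are local
  minima: little contact crosses them.
- **Boundary test.** Candidates are strict local minima. The
  prominence `delta` is the mean score of the two flanking local
  maxima minus the candidate score; candidates need `delta >= 0.01`.
  Significance comes from two one-sided Mann-Whitney tests comparing
  the candidate's diamond z-values with each flanking maximum's
  diamond (alternative: the candidate is lower), keeping the larger of
  the two p-values — the boundary must beat *both* flanks. P-values
  are BH-adjusted over all candidates genome-wide and accepted at
  q <= 0.05. This is a from-scratch reimplementation of the
  separation-score approach; it is not bit-compatible with other
  implementations of the same idea. The published parameter listing
  this follows states the delta rule as "delta < 0.01", which
  contradicts a prominence reading; chromoshift requires
  `delta >= 0.01`, matching the underlying tool's semantics.
- **Domains.** Consecutive accepted boundaries delimit domains, with
  chromosome ends implicit. Domains below the minimum size (3 bins by
  default, i.e. 15 kb at 5-kb resolution — the smallest window) are
  merged by dissolving the *weaker* (higher-score) of their two
  delimiting boundaries; the stronger boundary is the one better
  supported by the data, so it survives.

Cross-condition comparisons: shared TADs require reciprocal overlap of
at least 80% of both domains (greedy one-to-one matching by descending
overlap); a boundary is *lost* when no condition-2 boundary lies
within one bin of it (both the fraction and the tolerance are
exposed); size distributions are compared with two-sided Mann-Whitney
tests, optionally stratified by each domain's majority compartment.

## Contact partitioning and decay change

Contact mass is classed by bin-pair separation into cis-short
(< 20 kb), cis-long (>= 20 kb; a tie at exactly 20 kb goes to long,
since "short" is defined strictly) and trans. Fractions weight by
count mass over all valid contacts. The decay-change curve
depth-normalizes both matrices to equal total cis count, averages
contact per log-spaced distance stratum (zeros included, with the pair
count taken from the genome geometry) and reports
$\log_2(\text{cond2}/\text{cond1})$. Interaction strength by
compartment-label pair averages O/E over A-A, B-B and A-B bin pairs,
sharing the same expected model as compartment calling.

## Expression and accessibility integration

FPKM is count / ((length/10^3)(library/10^6)). Differential calls use
log2 fold changes of mean FPKM with a pseudocount of 1 (the fold
change of high-coverage features is insensitive to halving it), and a
two-sided moderated t-test (limma's empirical-Bayes variance
shrinkage) on log2(FPKM + 1). Moderation borrows variance strength
across features; with only two or three replicates per condition a
plain per-feature test has essentially no power at stringent FDR
cutoffs, while the moderated test recovers planted effects reliably.
This engine is a deliberate stand-in for a negative-binomial GLM:
users with DESeq2 or DiffBind output can inject it via
`external_expression_stats()` / the `external` argument of
`differential_peaks()`, and every downstream statistic only needs the
(log2FC, adjusted p) table. DEGs require |log2FC| >= 1 and adjusted
p < 0.01; differential peaks require adjusted p < 0.05 only.

Features are assigned to bins, switch classes and TADs by midpoint
containment — deterministic, strand-free and exclusive. Switch-region
expression shifts compare the fold changes of features in each
switching class against all features (two-sided Mann-Whitney).
Within-TAD co-regulation compares the SD of member-gene fold changes
per TAD (>= 3 genes) against size-matched random gene sets sampled
genome-wide without replacement, 100+ rounds per TAD, with a
Mann-Whitney test of TAD SDs versus the pooled random SDs. Because the
pooled random SDs are drawn from one shared gene pool they are
positively correlated, which deflates the rank-sum variance relative
to its independence assumption: the resulting p-value is
*conservative* under the null (verified by simulation: no excess of
small p-values at any level, while strongly coupled effects still give
p << 0.01). The switch-shift p-values are uniform under the null.

Metagene profiles average per-condition CPM coverage over features on
a grid of fixed-bp flanks (10 points per 1-kb flank) plus a
length-scaled body (20 points). The grid is built mirror-symmetric and
minus-strand features sample reflected positions, so reversing all
strands reverses the profile exactly — a property the tests exploit.
Peak "occupancy" is counts-per-million per sample, averaged within
condition. Promoters are the 1-kb window upstream of the TSS on the
coding strand; peak feature classes use midpoint precedence
promoter > gene body > intergenic. Association of differential peaks
with switch regions uses the two-sided Fisher exact test with the
cross-product odds ratio. Overlap enrichment between arbitrary
interval sets uses a circular-shift permutation null (independent
uniform per-chromosome shift, lengths and spacings preserved,
wrap-around intervals split) with empirical
p = (1 + #{null >= obs}) / (1 + n).

## The synthetic-data generator

All recovery claims are validated against `sim_config()` /
`simulate_bundle()`, which emulate the statistical structure the
analyses assume, with known truth:

- **Hi-C.** Poisson counts with expected cis intensity
  $\lambda(i,j) \propto d^{-\alpha}\,(1 + c\,s_i s_j)\,(\tau$ if same
  TAD$)$, scaled so the matrix totals the configured depth; $s = +1$
  in A blocks, $-1$ in B. The diagonal is treated as $d = 1$. Trans
  pairs are uniform Poisson background (defaults give roughly 9%
  trans mass). Condition 2 flips a fraction of compartment blocks,
  deletes a fraction of TAD boundaries, and uses its own exponent.
- **Defaults are the study conditions.** Two 10-Mb chromosomes
  generated at 5 kb and aggregated to 100 kb; checkerboard strength
  c = 0.4; alternating A/B blocks with geometric lengths (mean 1 Mb);
  TAD boundaries every 200 kb; within-TAD enrichment tau = 2; 10% of
  blocks flipped; 30% of boundaries deleted; depth 10^6 contacts per
  matrix; decay exponents (1.3, 1.0) so the condition-2 matrix is
  depleted of short-range cis contact, the stress phenotype under
  study. TAD boundaries are offset by half a compartment bin so they
  never coincide with block edges: checkerboard edges insulate on
  their own, and without the offset a "deleted" boundary that sits on
  a block edge would remain detectable, conflating switch and
  boundary-loss effects.
- **Expression.** 2000 genes placed with 3:1 odds in A blocks (the A
  compartment must be gene-rich for the orientation rule); 1000 TEs
  with the reciprocal bias. Condition-2 log2 fold change = beta times
  the switch direction at the gene midpoint (+2 for B->A by default),
  plus a TAD-shared Normal(0, 0.5) component and Normal(0, 0.3) gene
  noise; replicate counts are log-normal-Poisson (dispersion 0.15)
  around condition means at 10^6 library size, 3 replicates.
- **ATAC.** Peaks at the TSS of 60% of genes plus 400 intergenic
  background peaks, 2-fold elevated in A bins; peaks over flipped
  blocks are truly differential with probability 0.8 and shift
  4-fold in the switch direction; 2 replicates.

What the generator does *not* emulate: restriction-fragment geometry,
mappability and GC bias, copy-number variation, overdispersed
(negative-binomial) Hi-C counts, nested/hierarchical TADs, loops, and
isoform structure. Passing recovery tests therefore demonstrate that
the estimators are correct and well calibrated under the assumed
model, not that they are robust to every artifact of real libraries;
for real data the external DESeq2/DiffBind injection points and the
documented masks are the intended path.

## Problem sizes, determinism and other choices

The test and acceptance workloads use the 2 x 10 Mb toy genome —
4000 bins at 5 kb, 200 at 100 kb — which exercises every code path in
tens of seconds while leaving Poisson noise realistic at depth 10^6.
All randomness flows through explicit seeds (`sim_config(seed=)`,
`tad_coregulation(seed=)`, permutation seeds), and the pipeline writes
no timestamps into its report, so a fixed config and seed reproduce a
byte-identical report directory. Stage caching between runs was
considered and rejected: it adds state that could silently break that
guarantee, and single-pass runs are cheap at this scale. With the
generator's regular boundary spacing, deleting 30% of boundaries
right-shifts the TAD size distribution while the sample *median* can
stay at exactly one spacing unit; directional claims about TAD size
are therefore tested with one-sided rank-sum statistics and means.

Known limitations: compartment calls need >= 3 unmasked bins and a
positive leading eigenvalue per chromosome; very short chromosomes
(under twice the largest window) cannot be scored for TADs; the
moderated-t stand-in shares limma's assumption of roughly comparable
log-scale variances across features; and the Fisher association
treats peaks as exchangeable units, ignoring spatial autocorrelation
(the permutation test is the spatially aware alternative).
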