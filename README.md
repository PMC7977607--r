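# chromoshift

Comparative analysis of 3D chromatin architecture between two
conditions — e.g. a control and a heat-stressed sample — from binned
Hi-C contact matrices, integrated with gene expression and chromatin
accessibility. The package targets the standard questions of a
two-condition Hi-C study in plants or other compact genomes: which
genomic bins switch A/B compartment, which TAD boundaries disappear,
how the contact distance spectrum shifts, and how those architectural
changes couple to differential expression and differential ATAC peaks.

## What it computes

**A/B compartments.** Per chromosome, contacts are normalized to
observed/expected (O/E) against the mean contact at each distance; PC1
is the leading eigenvector of the Pearson correlation matrix of the
O/E rows, scaled by the root of its eigenvalue and sign-oriented so it
correlates positively with gene density (A = gene-rich). Bins are
labeled by the sign of PC1, and two profiles are combined into per-bin
switch classes A-A / B-B / A-B / B-A with a small |PC1| dead zone
against sign noise.

**TADs.** A z-score matrix standardizes contacts within each distance
stratum (population sd); the TAD-separation score at each boundary is
the mean z over the inter-window "diamond", averaged over window sizes
of 15–30 kb in 5-kb steps. Boundaries are strict local minima passing
a prominence threshold (delta >= 0.01) and a BH-adjusted (q <= 0.05)
one-sided rank-sum test of the boundary diamond against both flanking
maxima. Domains between accepted boundaries are compared across
conditions: shared TADs by 80% reciprocal overlap, size distributions
by rank-sum tests, and lost boundaries (no partner within ±1 bin)
annotated by the local compartment-switch class.

**Contacts.** Count mass is partitioned into cis-short (< 20 kb),
cis-long and trans; a depth-normalized log2 decay-ratio curve
localizes where along the distance axis one condition gains or loses
contact; mean O/E is aggregated by compartment-label pair (A-A, B-B,
A-B).

**Integration.** FPKM, log2 fold changes and a moderated-t
differential test (limma engine; DESeq2/DiffBind tables can be
injected instead), the paper-standard DEG rule |log2FC| >= 1 &
padj < 0.01; fold-change shifts of genes/TEs in switch regions
(Mann-Whitney vs all genes); within-TAD co-regulation of fold changes
vs size-matched random gene sets; strand-aware metagene profiles of
ATAC signal around genes or TADs; Fisher association of differential
peaks with switch segments; differential-peak load in domains with vs
without boundary loss; and circular-shift permutation tests for
interval overlap enrichment.

**Synthetic truth.** `sim_config()` / `simulate_bundle()` generate a
condition-paired Hi-C + RNA + ATAC bundle with known ground truth
(Poisson checkerboard contacts with distance decay and TAD blocks,
planted compartment flips, boundary deletions, coupled expression and
peak shifts), which is how every estimator in the package is
validated.

## Worked example

```r
library(chromoshift)

cfg <- sim_config(seed = 1)        # default two-condition study
b   <- simulate_bundle(cfg)

p1 <- call_compartments(b$hic_comp[[1]], b$genes)
p2 <- call_compartments(b$hic_comp[[2]], b$genes)
sw <- classify_switches(p1, p2)
sw$bin_counts
#> A-A B-B A-B B-A
#>  79 103   0  18

call_tads <- function(m) {
  z  <- zscore_matrix(m, 55000)
  bc <- call_boundaries(separation_score(z, 5000 * (3:6)), z)
  domains_from_boundaries(bc, m$genome)
}
t1 <- call_tads(b$hic[[1]]); t2 <- call_tads(b$hic[[2]])
t1
#> tad_set: 113 domains, median size 200000 bp
t2
#> tad_set: 79 domains, median size 200000 bp

gl <- setNames(b$genes$end - b$genes$start, b$genes$id)
es <- differential_expression(b$rna$counts, gl)
sum(es$de)
#> [1] 315
switch_region_shift(es, sw, b$genes)[, 1:5]
#>   class   n median_l2fc control_median       pvalue
#> 1   A-B   0          NA     -0.2584645           NA
#> 2   B-A 107    1.212953     -0.2584645 4.782274e-56
```

Under this seed, 18 of 200 bins flip B→A in condition 2 (and the
caller finds exactly those); deleting 30% of boundaries shrinks the
condition-2 TAD count from 113 to 79 while sizes grow; and the genes
inside B→A regions are strongly upregulated (median log2FC +1.21)
relative to all genes.

The full pipeline runs from a YAML config and writes one TSV per
result panel plus a JSON index:

```r
run_pipeline("run.yaml")   # or: Rscript inst/cli/chromoshift.R run --config run.yaml
```

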