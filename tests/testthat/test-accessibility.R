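# Metagene profiles, differential peaks, feature classification,
# Fisher association, boundary-loss peak load, overlap permutation and
# expression-by-peak splits.

make_signal <- function(peaks, cpm1, cpm2) {
  list(peaks = peaks, cpm = cbind(cond1 = cpm1, cond2 = cpm2),
       conditions = c("cond1", "cond2"))
}

test_that("metagene profile is flat on constant signal and linear", {
  g <- genome_spec(c(chr1 = 1e6), 5000)
  # one peak covering the whole chromosome = constant signal
  cover <- intervals("chr1", 0, 1e6, kind = "peak")
  sig <- make_signal(cover, 3, 5)
  feats <- intervals("chr1", seq(2e5, 6e5, by = 1e5),
                     seq(2e5, 6e5, by = 1e5) + 20000,
                     strand = c("+", "-", "+", "-", "+"), kind = "gene")
  mp <- metagene_profile(sig, feats, g)
  m1 <- mp$profile$mean[mp$profile$condition == "cond1"]
  expect_true(all(m1 == 3))
  # linearity: profile of summed signal = sum of profiles
  sigA <- make_signal(cover, 2, 2)
  sigB <- make_signal(cover, 1, 3)
  mpA <- metagene_profile(sigA, feats, g)
  mpB <- metagene_profile(sigB, feats, g)
  expect_equal(mpA$profile$mean + mpB$profile$mean, mp$profile$mean)
})

test_that("profile peaks at the TSS and strand reversal is symmetric", {
  b <- default_bundle()
  sig <- peak_signal(b$atac$peaks, b$atac$counts)
  g <- b$cfg$genome
  mp <- metagene_profile(sig, b$genes, g, flank = 1000, body_bins = 20,
                         flank_bins = 10)
  m1 <- mp$profile$mean[mp$profile$condition == "cond1"]
  # maximum sits within one grid step of the TSS (grid position 11)
  expect_lte(abs(which.max(m1) - 11), 1)
  # flipping every strand of a strand-balanced set flips the profile
  flipped <- b$genes
  flipped$strand <- ifelse(b$genes$strand == "+", "-", "+")
  mp_f <- metagene_profile(sig, flipped, g)
  m1f <- mp_f$profile$mean[mp_f$profile$condition == "cond1"]
  expect_equal(m1f, rev(m1), tolerance = 0.15)
})

test_that("differential peaks: null, planted recovery, external override", {
  set.seed(20)
  cm <- sapply(1:4, function(i) rpois(300, 50))
  rownames(cm) <- sprintf("p%03d", 1:300)
  colnames(cm) <- paste0("s", 1:4)
  ct <- count_table(cm, rep(c("c1", "c2"), each = 2))
  ps <- differential_peaks(ct)
  expect_equal(sum(ps$differential), 0)
  # planted recovery on the default bundle
  b <- default_bundle()
  pstats <- differential_peaks(b$atac$counts, b$atac$peaks)
  truly <- names(b$atac$true_diff)[b$atac$true_diff]
  expect_gte(mean(pstats$differential[match(truly, pstats$feature_id)]), 0.8)
  # external BED override: flags match the provided set exactly
  ext <- differential_peaks(ct, external = c("p001", "p100"))
  expect_equal(ext$feature_id[ext$differential], c("p001", "p100"))
})

test_that("peak feature classes follow promoter > gene body > intergenic", {
  genes <- intervals(c("chr1", "chr1"), c(10000, 30000), c(15000, 35000),
                     strand = c("+", "-"), kind = "gene")
  peaks <- intervals(rep("chr1", 4),
                     c(9400, 12000, 35200, 50000),
                     c(9600, 12400, 35600, 50400), kind = "peak")
  cls <- classify_peak_features(peaks, genes, promoter_bp = 1000)
  # 500 bp upstream of a + TSS; inside a gene body; 400 bp downstream of
  # a - gene end = upstream of its TSS; gene-free region
  expect_equal(cls, c("promoter", "gene_body", "promoter", "intergenic"))
  g2 <- genome_spec(c(chr1 = 1e5, chr2 = 1e5), 1e4)
  p2 <- intervals("chr2", 100, 200, kind = "peak")
  expect_equal(classify_peak_features(p2, genes), "intergenic")
})

test_that("Fisher association matches brute-force hypergeometric", {
  # printed example: (10,20,30,40) -> OR = 0.6667
  peaks <- intervals("chr1", seq(0, 99) * 1000, seq(0, 99) * 1000 + 100,
                     kind = "peak")
  is_diff <- rep(c(TRUE, FALSE), c(30, 70))
  # regions covering the first 10 diff and first 30 nondiff midpoints
  regions <- intervals("chr1",
                       c(0, 30000), c(10000, 60000), kind = "block")
  fa <- fisher_association(peaks, is_diff, regions)
  expect_equal(unname(fa$table[1, ]), c(10, 20))
  expect_equal(unname(fa$table[2, ]), c(30, 40))
  expect_equal(fa$odds_ratio, (10 * 40) / (20 * 30))
  # oracle: two-sided exact p by dhyper enumeration over small tables
  fisher_brute <- function(a, b, c_, d) {
    m <- a + c_; n_ <- b + d; k <- a + b
    xs <- max(0, k - n_):min(k, m)
    probs <- dhyper(xs, m, n_, k)
    sum(probs[probs <= dhyper(a, m, n_, k) * (1 + 1e-7)])
  }
  set.seed(21)
  for (i in 1:25) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p_ref <- fisher_brute(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_lt(abs(fisher.test(tab)$p.value - p_ref), 1e-10)
  }
  expect_true(fisher_association(peaks, is_diff,
                                 regions[0, , drop = FALSE])$flagged)
})

test_that("differential peaks concentrate in boundary-loss domains", {
  b <- default_bundle()
  ps <- differential_peaks(b$atac$counts, b$atac$peaks)
  fit1 <- default_tads(1); fit2 <- default_tads(2)
  lb <- lost_boundaries(fit1$tads, fit2$tads, tol = 1)
  d2 <- fit2$tads$domains
  has_loss <- vapply(seq_len(nrow(d2)), function(r)
    any(lb$lost$chrom == d2$chrom[r] & lb$lost$pos > d2$start[r] &
          lb$lost$pos < d2$end[r]), logical(1))
  res <- boundary_loss_peak_counts(b$atac$peaks, ps$differential,
                                   d2[has_loss, ], d2[!has_loss, ])
  expect_equal(nrow(res), 2)
  expect_true(all(res$n_diff_peaks >= 0))
  expect_error(boundary_loss_peak_counts(b$atac$peaks, ps$differential,
                                         d2, d2), "overlapping")
  # no differential peaks -> zeros
  res0 <- boundary_loss_peak_counts(b$atac$peaks,
                                    rep(FALSE, nrow(b$atac$peaks)),
                                    d2[has_loss, ], d2[!has_loss, ])
  expect_equal(res0$n_diff_peaks, c(0, 0))
})

test_that("circular-shift permutation detects planted co-location", {
  g <- genome_spec(c(chr1 = 1e6, chr2 = 1e6), 1000)
  set.seed(22)
  # set2: 20 scattered anchor regions
  anchors <- sort(sample(seq(0, 9.8e5, by = 1000), 20))
  set2 <- intervals(rep(c("chr1", "chr2"), each = 10),
                    rep(anchors[1:10], 2), rep(anchors[1:10], 2) + 5000,
                    kind = "site")
  # set1: half planted on anchors, half random
  on <- sample(10, 25, replace = TRUE)
  s1_start <- c(set2$start[on] + 1000,
                sample(seq(0, 9.9e5, by = 500), 25))
  set1 <- intervals(rep("chr1", 50), s1_start, s1_start + 500,
                    kind = "peak")
  res <- interval_overlap_enrichment(set1, set2, g, n_perm = 500, seed = 5)
  expect_lte(res$pvalue, 0.01)
  expect_gte(res$pvalue, 1 / 501)
  # determinism given the seed
  res2 <- interval_overlap_enrichment(set1, set2, g, n_perm = 500, seed = 5)
  expect_identical(res$pvalue, res2$pvalue)
  # set2 covering everything: observed = |set1|, p = 1
  whole <- intervals(c("chr1", "chr2"), c(0, 0), c(1e6, 1e6), kind = "site")
  res_all <- interval_overlap_enrichment(set1, whole, g, n_perm = 100,
                                         seed = 1)
  expect_equal(res_all$observed, nrow(set1))
  expect_equal(res_all$pvalue, 1)
})

test_that("genes with promoter/body peaks are higher expressed", {
  b <- default_bundle()
  gl <- setNames(b$genes$end - b$genes$start, b$genes$id)
  es <- differential_expression(b$rna$counts, gl)
  # couple peaks to the top-expressed half of genes
  ord <- order(-es$mean_fpkm1)
  top <- b$genes[match(es$feature_id[ord[1:600]], b$genes$id), ]
  tss <- ifelse(top$strand == "-", top$end - 1, top$start)
  peaks <- intervals(top$chrom, pmax(tss - 200, 0), tss + 200,
                     kind = "peak")
  res <- expression_by_peak_presence(es, peaks, b$genes)
  expect_lt(res$pvalue, 0.01)
  expect_gt(median(res$with_peak), median(res$without_peak))
  # all genes peaked: flagged, no test
  cover <- intervals(rep(c("chr1", "chr2"), each = 1), c(0, 0),
                     c(1e7, 1e7), kind = "peak")
  res_all <- expression_by_peak_presence(es, cover, b$genes)
  expect_true(res_all$flagged)
})
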