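# FPKM identities, the differential engine, switch-region shifts and
# within-TAD co-regulation.

test_that("fpkm matches its closed form and normalization identities", {
  cm <- matrix(c(10, 0, 999990, 0, 5, 999995), 3, 2,
               dimnames = list(c("a", "b", "filler"), c("s1", "s2")))
  ct <- count_table(cm, c("x", "y"))
  fk <- fpkm(ct, c(a = 1000, b = 2000, filler = 1e6))
  expect_equal(fk["a", "s1"], 10)  # 10 / (1 * 1)
  expect_equal(fk["b", "s1"], 0)
  # doubling all counts in a sample leaves FPKM unchanged
  ct2 <- count_table(cbind(s1 = 2 * cm[, 1], s2 = cm[, 2]), c("x", "y"))
  expect_equal(fpkm(ct2, c(a = 1000, b = 2000, filler = 1e6))[, "s1"],
               fk[, "s1"])
  # FPKM inversely proportional to length
  fk2 <- fpkm(ct, c(a = 2000, b = 2000, filler = 1e6))
  expect_equal(fk2["a", "s1"], fk["a", "s1"] / 2)
  expect_error(fpkm(ct, c(a = 0, b = 1, filler = 1)), "> 0")
})

test_that("BH adjustment matches the hand-computed oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # hand BH: q_i = min over j >= i of p_(j) * m / j, all = 0.04 here
  expect_equal(p.adjust(p, method = "BH"), rep(0.04, 4))
  q <- p.adjust(c(0.04, 0.001, 0.02), method = "BH")
  expect_true(all(q >= c(0.04, 0.001, 0.02)))
})

test_that("differential engine flags nothing under identical conditions", {
  set.seed(19)
  mu <- rlnorm(500, log(100), 1)
  cm <- sapply(1:6, function(i) rpois(500, mu))
  rownames(cm) <- sprintf("g%03d", 1:500)
  colnames(cm) <- paste0("s", 1:6)
  ct <- count_table(cm, rep(c("c1", "c2"), each = 3))
  es <- differential_expression(ct, setNames(rep(1000, 500), rownames(cm)))
  expect_false(any(es$de))
  # pseudocount robustness: halving it barely moves high-count log2FC
  es2 <- differential_expression(ct, setNames(rep(1000, 500), rownames(cm)),
                                 pseudocount = 0.5)
  hi <- es$mean_fpkm1 > quantile(es$mean_fpkm1, 0.75)
  expect_lt(max(abs(es$log2fc[hi] - es2$log2fc[hi])), 0.01)
})

test_that("planted switch effects are recovered as DEGs", {
  b <- default_bundle()
  gl <- setNames(b$genes$end - b$genes$start, b$genes$id)
  es <- differential_expression(b$rna$counts, gl)
  strong <- names(b$rna$true_l2fc)[abs(b$rna$true_l2fc) >= 1.5]
  expect_gte(mean(es$de[match(strong, es$feature_id)]), 0.8)
  # external table override preserves the flags contract
  ext <- external_expression_stats(data.frame(
    feature_id = c("x", "y"), log2fc = c(2, 0.5), padj = c(0.001, 0.001)))
  expect_equal(ext$de, c(TRUE, FALSE))
})

test_that("switch-region genes shift as planted, with exact symmetry", {
  b <- default_bundle()
  sw <- default_switches()
  gl <- setNames(b$genes$end - b$genes$start, b$genes$id)
  es <- differential_expression(b$rna$counts, gl)
  sh <- switch_region_shift(es, sw, b$genes)
  ba <- sh[sh$class == "B-A", ]
  if (ba$n >= 50) {
    expect_gt(ba$median_l2fc, ba$control_median)
    expect_lt(ba$pvalue, 0.01)
  }
  # swapping the condition order maps B-A onto A-B exactly
  pr <- default_profiles()
  sw_rev <- classify_switches(pr$p2, pr$p1)
  sh_rev <- switch_region_shift(es, sw_rev, b$genes)
  expect_equal(sh_rev[sh_rev$class == "A-B", "n"], ba$n)
  # no switching bins: classes empty and flagged
  sw_same <- classify_switches(pr$p1, pr$p1)
  sh_same <- switch_region_shift(es, sw_same, b$genes)
  expect_true(all(sh_same$flagged))
})

test_that("TAD co-regulation detects shared effects and respects the null", {
  cfg <- sim_config(seed = 1)
  tr <- simulate_truth(cfg)
  feats <- simulate_features(cfg, tr)
  truth_tads <- domains_from_boundaries(
    data.frame(chrom = tr$boundaries1$chrom, pos = tr$boundaries1$pos,
               score = 0, accepted = TRUE), cfg$genome)
  gl <- setNames(feats$genes$end - feats$genes$start, feats$genes$id)
  run_coreg <- function(cfg_i) {
    rna <- simulate_expression(cfg_i, tr, feats$genes)
    es <- differential_expression(rna$counts, gl)
    tad_coregulation(es, truth_tads, feats$genes, n_random = 100, seed = 7)
  }
  # sigma_tad-dominated: TAD SDs clearly below random SDs
  strong <- run_coreg(sim_config(sigma_tad = 1, gene_noise_sd = 0.2,
                                 beta = 0, seed = 1))
  expect_lt(median(strong$tad_sd), median(strong$random_sd))
  expect_lt(strong$pvalue, 0.01)
  # no shared TAD effect: non-significant at alpha = 0.01
  null <- run_coreg(sim_config(sigma_tad = 0, beta = 0, seed = 1))
  expect_gt(null$pvalue, 0.01)
  # a single TAD holding all genes: TAD SD equals a full-sample SD
  one <- tadset_from_sizes(2e7, genome_spec(c(chr1 = 1e7, chr2 = 1e7), 5000))
  one$domains <- data.frame(chrom = c("chr1", "chr2"), start = 0,
                            end = 1e7, size = 1e7)
  rna <- simulate_expression(cfg, tr, feats$genes)
  es <- differential_expression(rna$counts, gl)
  cr <- tad_coregulation(es, one, feats$genes, n_random = 100, seed = 3)
  expect_equal(length(cr$tad_sd), 2)
  expect_lt(abs(median(cr$tad_sd) - median(cr$random_sd)), 0.05)
})
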