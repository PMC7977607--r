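# Generator contracts: determinism, distance decay, depth scaling,
# checkerboard strength, planted expression and accessibility effects.

test_that("same seed reproduces the identical bundle, depth scales totals", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), depth = 2e5, seed = 11)
  a <- simulate_hic(cfg, 1)
  b <- simulate_hic(cfg, 1)
  expect_identical(a$matrix$count, b$matrix$count)
  expect_identical(a$matrix$i, b$matrix$i)
  # no planted differences => condition-2 truth equals condition 1
  cfg0 <- sim_config(chrom_lengths = c(chr1 = 2e6), f_switch = 0,
                     f_loss = 0, seed = 3)
  tr <- simulate_truth(cfg0)
  expect_identical(tr$label1, tr$label2)
  expect_equal(nrow(tr$deleted_boundaries), 0)
  # marginal sums scale linearly with depth (5% tolerance)
  cfg1 <- sim_config(chrom_lengths = c(chr1 = 2e6), depth = 1e5,
                     trans_rate = 0, seed = 5)
  cfg2 <- sim_config(chrom_lengths = c(chr1 = 2e6), depth = 4e5,
                     trans_rate = 0, seed = 5)
  s1 <- sum(simulate_hic(cfg1, 1)$matrix$count)
  s2 <- sum(simulate_hic(cfg2, 1)$matrix$count)
  expect_lt(abs(s2 / s1 - 4), 4 * 0.05)
})

test_that("with c = 0 and tau = 1 the mean contact follows the power law", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2.5e6), c_strength = 0,
                    tau = 1, alpha = c(1, 1), depth = 5e5,
                    trans_rate = 0, seed = 2)
  m <- simulate_hic(cfg, 1)$matrix
  em <- expected_by_distance(m, "chr1")
  d <- 2:80  # away from the d<=1 diagonal convention and sparse tail
  fit <- lm(log(em[d + 1]) ~ log(d))
  expect_lt(abs(coef(fit)[2] - (-1)), 0.05)
})

test_that("checkerboard strength gives the (1+c)/(1-c) same/opposite ratio", {
  cfg <- sim_config(tau = 1, seed = 4)
  hic <- simulate_hic(cfg, 1)
  mc <- aggregate_matrix(hic$matrix, cfg$compartment_bin)
  g <- mc$genome
  ratio_all <- c()
  for (k in seq_along(g$chrom)) {
    oe <- chromoshift:::oe_chrom(mc, g$chrom[k])
    s <- hic$truth$label1[(g$offset[k] + 1):(g$offset[k] + g$n_bins[k])]
    pr <- which(upper.tri(oe), arr.ind = TRUE)
    d <- pr[, 2] - pr[, 1]
    same <- s[pr[, 1]] == s[pr[, 2]]
    v <- oe[pr]
    # per-distance stratification, strata with both classes present
    for (dd in unique(d)) {
      sel <- d == dd
      if (sum(sel & same) >= 10 && sum(sel & !same) >= 10)
        ratio_all <- c(ratio_all,
                       mean(v[sel & same], na.rm = TRUE) /
                         mean(v[sel & !same], na.rm = TRUE))
    }
  }
  target <- (1 + cfg$c_strength) / (1 - cfg$c_strength)
  expect_lt(abs(median(ratio_all) - target) / target, 0.15)
})

test_that("planted expression effects have the stated structure", {
  cfg <- sim_config(seed = 6)
  tr <- simulate_truth(cfg)
  feats <- simulate_features(cfg, tr)
  # null couplings give ~zero planted fold changes and no DE flags
  cfg0 <- sim_config(beta = 0, sigma_tad = 0, gene_noise_sd = 0, seed = 6)
  rna0 <- simulate_expression(cfg0, tr, feats$genes)
  expect_true(all(abs(rna0$true_l2fc) < 1e-12))
  expect_false(any(rna0$true_de))
  # genes in B->A blocks carry +beta on average (construction)
  rna <- simulate_expression(cfg, tr, feats$genes)
  mid_bin <- bin_of(feats$genes$chrom, midpoints(feats$genes),
                    cfg$genome_comp) + 1L
  ba <- tr$label1[mid_bin] < 0 & tr$label2[mid_bin] > 0
  if (any(ba)) {
    expect_lt(abs(mean(rna$true_l2fc[ba]) - cfg$beta),
              3 * sqrt(cfg$sigma_tad^2 + cfg$gene_noise_sd^2) / sqrt(sum(ba)) + 0.3)
  }
  # empirical log2FC of high-count genes recovers the planted values
  gl <- setNames(feats$genes$end - feats$genes$start, feats$genes$id)
  es <- differential_expression(rna$counts, gl)
  hi <- es$mean_fpkm1 > quantile(es$mean_fpkm1, 0.5)
  err <- es$log2fc[hi] - rna$true_l2fc[es$feature_id[hi]]
  expect_lt(median(abs(err)), 0.3)
})

test_that("ATAC coupling flags follow the switch blocks as configured", {
  tr <- simulate_truth(sim_config(seed = 8))
  feats <- simulate_features(sim_config(seed = 8), tr)
  # coupling 1: every peak over a flipped block is flagged
  cfg1 <- sim_config(coupling_prob = 1, seed = 8)
  a1 <- simulate_atac(cfg1, tr, feats$genes)
  over_switch <- a1$true_dir != 0
  expect_true(all(a1$true_diff[over_switch]))
  expect_false(any(a1$true_diff[!over_switch]))
  # coupling 0: nothing flagged
  cfg0 <- sim_config(coupling_prob = 0, seed = 8)
  a0 <- simulate_atac(cfg0, tr, feats$genes)
  expect_false(any(a0$true_diff))
  # peak tables survive the genome_model writers
  d <- withr::local_tempdir()
  write_intervals(a1$peaks, file.path(d, "p.bed"))
  p2 <- read_intervals(file.path(d, "p.bed"), kind = "peak")
  expect_equal(p2$start, a1$peaks$start)
  write_counts(a1$counts, file.path(d, "c.tsv"))
  expect_equal(read_counts(file.path(d, "c.tsv"))$counts, a1$counts$counts)
})
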