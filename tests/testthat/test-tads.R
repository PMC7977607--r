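# z-score matrix, separation score, boundary calling, domain
# construction and cross-condition TAD comparison.

test_that("z-scores standardize each distance stratum (population sd)", {
  # stratum with values (1,2,3): z = (-1.2247, 0, 1.2247)
  x <- matrix(0, 4, 4)
  x[cbind(1:3, 2:4)] <- c(1, 2, 3)
  x <- x + t(x)
  diag(x) <- 5
  m <- cm_from_dense(x, 10)
  z <- zscore_matrix(m, 30)
  expect_equal(z$z$chrA[cbind(1:3, 2:4)],
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  # constant stratum (diagonal): sd = 0 rule gives z = 0
  expect_equal(diag(z$z$chrA), rep(0, 4))
  # by construction each stratum has mean ~0 and population sd ~1
  set.seed(12)
  x <- matrix(rpois(30 * 30, 6), 30, 30)
  x <- x + t(x)
  m <- cm_from_dense(x, 10)
  z <- zscore_matrix(m, 200)
  for (d in 1:20) {
    v <- z$z$chrA[cbind(1:(30 - d), (1 + d):30)]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  }
  # full-matrix oracle: brute-force two-pass standardization
  for (d in 0:20) {
    idx <- cbind(1:(30 - d), (1 + d):30)
    v <- x[idx]
    mu <- mean(v); sg <- sqrt(mean((v - mu)^2))
    zo <- if (sg > 0) (v - mu) / sg else rep(0, length(v))
    expect_lt(max(abs(z$z$chrA[idx] - zo)), 1e-10)
  }
})

test_that("separation score equals brute-force diamond means", {
  set.seed(13)
  x <- matrix(rpois(30 * 30, 6), 30, 30)
  x <- x + t(x)
  m <- cm_from_dense(x, 5000)
  z <- zscore_matrix(m, 11 * 5000)
  tr <- separation_score(z, window_sizes = 5000 * c(2, 4))
  zm <- z$z$chrA
  for (p in 4:26) {
    vals <- sapply(c(2, 4), function(w)
      mean(zm[(p - w + 1):p, (p + 1):(p + w)]))
    expect_lt(abs(tr$score$chrA[p] - mean(vals)), 1e-10)
  }
  # all-zero z gives an all-zero score
  z0 <- z
  z0$z$chrA[] <- 0
  tr0 <- separation_score(z0, window_sizes = 5000 * c(2, 4))
  expect_true(all(tr0$score$chrA[!is.na(tr0$score$chrA)] == 0))
})

test_that("block structure puts the score minimum at the block boundary", {
  # two 10-bin blocks with strong interior, weak inter-block contact
  x <- matrix(1, 20, 20)
  x[1:10, 1:10] <- 50
  x[11:20, 11:20] <- 50
  set.seed(14)
  x <- x + matrix(runif(400, 0, 0.1), 20, 20)
  x <- (x + t(x)) / 2
  m <- cm_from_dense(x, 5000)
  z <- zscore_matrix(m, 7 * 5000)
  tr <- separation_score(z, window_sizes = 5000 * c(2, 3, 4))
  s <- tr$score$chrA
  expect_equal(which.min(s), 10L)  # boundary between bins 10 and 11
})

test_that("boundary calling filters by delta and FDR, handles monotone", {
  # monotone track: no candidates
  g <- genome_spec(c(chrA = 20 * 5000), 5000)
  fake_track <- structure(list(
    genome = g, score = list(chrA = c(NA, NA, seq(-1, 1, length.out = 15),
                                      NA, NA)),
    by_window = NULL, window_bins = 2L, window_sizes = 10000),
    class = "separation_track")
  set.seed(15)
  x <- matrix(rpois(400, 5), 20, 20); x <- x + t(x)
  z <- zscore_matrix(cm_from_dense(x, 5000), 10 * 5000)
  calls <- call_boundaries(fake_track, z)
  expect_equal(nrow(calls), 0)
  # recovery on the default simulation: precision and recall >= 0.8
  b <- default_bundle()
  fit1 <- default_tads(1)
  acc <- fit1$calls[fit1$calls$accepted, ]
  tb <- b$truth$boundaries1
  tol <- b$hic[[1]]$genome$bin_size
  recall <- mean(near_any(tb$chrom, tb$pos, acc$chrom, acc$pos, tol))
  precision <- mean(near_any(acc$chrom, acc$pos, tb$chrom, tb$pos, tol))
  expect_gte(recall, 0.8)
  expect_gte(precision, 0.8)
})

test_that("boundary recovery improves with the TAD enrichment factor", {
  f1 <- function(tau, seed = 21) {
    cfg <- sim_config(chrom_lengths = c(chr1 = 4e6), tau = tau,
                      depth = 4e5, f_switch = 0, f_loss = 0, seed = seed)
    hic <- simulate_hic(cfg, 1)
    m <- hic$matrix
    z <- zscore_matrix(m, 11 * m$genome$bin_size)
    bc <- call_boundaries(separation_score(z, m$genome$bin_size * (3:6)), z)
    acc <- bc[bc$accepted, ]
    tb <- hic$truth$boundaries1
    r <- mean(near_any(tb$chrom, tb$pos, acc$chrom, acc$pos,
                       m$genome$bin_size))
    p <- if (nrow(acc)) mean(near_any(acc$chrom, acc$pos, tb$chrom, tb$pos,
                                      m$genome$bin_size)) else 0
    2 * r * p / max(r + p, 1e-9)
  }
  fs <- vapply(c(1.5, 2, 3), f1, numeric(1))
  expect_true(all(diff(fs) >= 0))
})

test_that("domains partition chromosomes and slivers merge", {
  g <- genome_spec(c(chr1 = 30 * 5000), 5000)
  mk_calls <- function(pos, score = rep(-1, length(pos))) {
    data.frame(chrom = rep("chr1", length(pos)), pos = pos, score = score,
               accepted = rep(TRUE, length(pos)), stringsAsFactors = FALSE)
  }
  # no boundaries: whole chromosome
  t0 <- domains_from_boundaries(mk_calls(numeric(0)), g)
  expect_equal(t0$domains$size, 150000)
  # boundaries at bins 10, 20 on a 30-bin chromosome
  t1 <- domains_from_boundaries(mk_calls(c(50000, 100000)), g)
  expect_equal(t1$domains$start, c(0, 50000, 100000))
  expect_equal(t1$domains$end, c(50000, 100000, 150000))
  # sliver merging: each sub-min domain removes one boundary, and the
  # weaker (higher-score) delimiter is dissolved
  t2 <- domains_from_boundaries(
    mk_calls(c(50000, 55000, 100000), score = c(-2, -1, -1.5)), g,
    min_size = 15000)
  expect_equal(nrow(t2$domains), nrow(t1$domains))
  expect_true(50000 %in% t2$boundaries$pos)   # stronger kept
  expect_false(55000 %in% t2$boundaries$pos)  # weaker dissolved
  # partition: union = chromosome, pairwise disjoint
  for (ts in list(t0, t1, t2)) {
    d <- ts$domains
    expect_equal(sum(d$size), 150000)
    expect_true(all(d$start[-1] == d$end[-nrow(d)]))
  }
})

test_that("reciprocal-overlap sharing follows the 80% rule", {
  g <- genome_spec(c(chr1 = 1e6), 5000)
  s1 <- tadset_from_sizes(c(100000, 900000), g)
  # [0,100k) vs [10k,100k): overlap 90k >= 80% of both -> shared
  s2 <- structure(list(genome = g,
    domains = data.frame(chrom = "chr1", start = c(10000, 100000),
                         end = c(100000, 1e6),
                         size = c(90000, 9e5)),
    boundaries = data.frame(chrom = "chr1", pos = 100000)),
    class = "tad_set")
  sh <- shared_tads(s1, s2)
  expect_equal(sh$n_shared, 2)
  # [0,100k) vs [50k,150k): overlap 50k < 80k -> not shared
  s3 <- structure(list(genome = g,
    domains = data.frame(chrom = "chr1", start = c(50000, 150000),
                         end = c(150000, 1e6),
                         size = c(100000, 850000)),
    boundaries = data.frame(chrom = "chr1", pos = 150000)),
    class = "tad_set")
  sh3 <- shared_tads(s1, s3)
  expect_equal(sh3$pairs$set1_idx, 2L)  # only the big domains pair up
  # identical sets are fully shared
  sh_id <- shared_tads(s1, s1)
  expect_equal(sh_id$n_shared, nrow(s1$domains))
  expect_equal(sh_id$n_set1_only, 0)
})

test_that("TAD size comparison reproduces the exact rank-sum p", {
  sa <- tadset_from_sizes(c(1, 2, 3))
  sb <- tadset_from_sizes(c(4, 5, 6))
  res <- compare_tad_sizes(sa, sb)
  # oracle: enumerate all C(6,3)=20 rank assignments
  pooled <- c(1, 2, 3, 4, 5, 6)
  combs <- combn(6, 3)
  w_obs <- sum(rank(pooled)[1:3])
  w_all <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]))
  mu <- mean(w_all)
  p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu))
  expect_equal(p_exact, 0.1)
  expect_equal(res$pvalue[res$stratum == "all"], p_exact, tolerance = 1e-12)
  # identical sets: p = 1
  expect_equal(compare_tad_sizes(sa, sa)$pvalue[1], 1)
})

test_that("deleted boundaries are flagged lost with switch annotation", {
  b <- default_bundle()
  fit1 <- default_tads(1)
  fit2 <- default_tads(2)
  # identical sets: zero lost
  self <- lost_boundaries(fit1$tads, fit1$tads, tol = 1)
  expect_equal(self$n_lost, 0)
  lb <- lost_boundaries(fit1$tads, fit2$tads, default_switches(), tol = 1)
  del <- b$truth$deleted_boundaries
  flagged <- mean(near_any(del$chrom, del$pos, lb$lost$chrom, lb$lost$pos,
                           b$hic[[1]]$genome$bin_size))
  expect_gte(flagged, 0.9)
  expect_equal(sum(lb$class_tally), sum(!is.na(lb$lost$switch_class)))
})
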