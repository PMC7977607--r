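# Synthetic condition-paired Hi-C / RNA / ATAC generator with ground truth.
#
# The contact model is a Poisson checkerboard: expected cis intensity
#   lambda(i,j) = depth * w(i,j) / sum(w),
#   w(i,j) = d^-alpha * (1 + c * s_i * s_j) * (tau if same TAD else 1)
# with s = +1 in A blocks and -1 in B blocks, d = |i - j| in bins (the
# diagonal is treated as d = 1). Condition 2 flips a fraction of
# compartment blocks, deletes a fraction of TAD boundaries and uses its
# own decay exponent. Trans pairs are uniform Poisson background.

#' Simulation configuration
#'
#' All downstream recovery tests run against data drawn from this model;
#' defaults describe a two-chromosome 20-Mb toy genome generated at 5-kb
#' resolution and aggregated to 100-kb for compartment work.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param bin_size Hi-C generation resolution (bp).
#' @param compartment_bin resolution at which compartment blocks are laid
#'   down and called (bp); must be a multiple of `bin_size`.
#' @param block_mean_bins mean compartment block length, in
#'   `compartment_bin` units (geometric distribution).
#' @param c_strength checkerboard strength `c` in (0,1).
#' @param alpha distance-decay exponents, one per condition. The default
#'   makes condition 2 shallower, so after depth normalization its
#'   short-range cis contacts are depleted relative to condition 1 (the
#'   stress phenotype the generator emulates).
#' @param tau within-TAD contact enrichment factor (>= 1).
#' @param tad_spacing_bins TAD boundary spacing in `bin_size` units.
#' @param tad_offset_bins offset of the first TAD boundary from the
#'   chromosome start, in `bin_size` units. The default (half a
#'   compartment bin) keeps TAD boundaries off the compartment block
#'   grid, so checkerboard edges and TAD boundaries never coincide and
#'   boundary-loss and switch events stay independently testable.
#' @param f_switch fraction of compartment blocks flipped in condition 2.
#' @param f_loss fraction of TAD boundaries deleted in condition 2.
#' @param depth expected total cis contact count per matrix.
#' @param trans_rate per-pair trans intensity as a fraction of `depth`
#'   (lambda_trans = depth * trans_rate).
#' @param n_genes,n_tes number of genes / transposable elements.
#' @param gene_density_ratio gene placement odds A : B (genes are
#'   A-enriched; TEs use the reciprocal ratio).
#' @param expr_meanlog,expr_sdlog log-normal baseline expression.
#' @param rna_depth expected library size per RNA replicate.
#' @param beta planted |log2 fold-change| on genes in flipped blocks
#'   (positive for B->A, negative for A->B).
#' @param sigma_tad sd of the TAD-shared log2FC component.
#' @param gene_noise_sd sd of gene-level log2FC noise.
#' @param rep_disp log-normal overdispersion sd of replicate counts.
#' @param n_reps_rna,n_reps_atac replicates per condition.
#' @param peak_frac_genes fraction of genes given a TSS ATAC peak.
#' @param n_bg_peaks intergenic background peaks.
#' @param peak_width ATAC peak width (bp).
#' @param atac_a_boost fold elevation of peak intensity in A bins.
#' @param coupling_prob probability that a peak over a flipped block is
#'   truly differential.
#' @param atac_shift_log2 |log2 shift| of truly differential peaks
#'   (sign follows the switch direction).
#' @param atac_meanlog,atac_sdlog log-normal baseline peak intensity.
#' @param atac_depth expected library size per ATAC replicate.
#' @param seed integer random seed; fixed seed gives byte-identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
                       bin_size = 5000,
                       compartment_bin = 100000,
                       block_mean_bins = 10,
                       c_strength = 0.4,
                       alpha = c(1.3, 1.0),
                       tau = 2,
                       tad_spacing_bins = 40,
                       tad_offset_bins = 10,
                       f_switch = 0.1,
                       f_loss = 0.3,
                       depth = 1e6,
                       trans_rate = 2.5e-8,
                       n_genes = 2000,
                       n_tes = 1000,
                       gene_density_ratio = 3,
                       expr_meanlog = log(200),
                       expr_sdlog = 1,
                       rna_depth = 1e6,
                       beta = 2,
                       sigma_tad = 0.5,
                       gene_noise_sd = 0.3,
                       rep_disp = 0.15,
                       n_reps_rna = 3,
                       n_reps_atac = 2,
                       peak_frac_genes = 0.6,
                       n_bg_peaks = 400,
                       peak_width = 400,
                       atac_a_boost = 2,
                       coupling_prob = 0.8,
                       atac_shift_log2 = 2,
                       atac_meanlog = log(100),
                       atac_sdlog = 0.8,
                       atac_depth = 5e5,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    compartment_bin %% bin_size == 0,
    c_strength >= 0, c_strength < 1,
    all(alpha > 0), length(alpha) == 2,
    tau >= 1,
    f_switch >= 0, f_switch <= 1,
    f_loss >= 0, f_loss <= 1,
    depth > 0, trans_rate >= 0,
    coupling_prob >= 0, coupling_prob <= 1,
    peak_frac_genes >= 0, peak_frac_genes <= 1,
    n_reps_rna >= 2, n_reps_atac >= 2
  )
  cfg$seed <- as.integer(seed)
  cfg$genome <- genome_spec(chrom_lengths, bin_size)
  cfg$genome_comp <- genome_spec(chrom_lengths, compartment_bin)
  class(cfg) <- "sim_config"
  cfg
}

#' Ground-truth architecture: compartment blocks and TAD boundaries
#'
#' Lays down alternating A/B blocks (geometric lengths) at the
#' compartment resolution, flips a fraction of them in condition 2,
#' places TAD boundaries at regular spacing at the Hi-C resolution and
#' deletes a fraction in condition 2. Compartment block edges and TAD
#' boundaries are decoupled so switch and boundary-loss effects can be
#' tested independently.
#'
#' @param cfg a [sim_config()].
#' @return list of class `truth_tables`: `label1`/`label2` (+1 A, -1 B per
#'   compartment bin), `blocks` (block table with `flipped`),
#'   `boundaries1`/`boundaries2` (bp positions per condition),
#'   `deleted_boundaries` (bp), and bookkeeping vectors.
#' @export
simulate_truth <- function(cfg) {
  set.seed(cfg$seed)
  gc_ <- cfg$genome_comp
  blocks <- list()
  label1 <- integer(0)
  for (k in seq_along(gc_$chrom)) {
    n <- gc_$n_bins[k]
    lab <- if (stats::runif(1) < 0.5) 1L else -1L
    pos <- 0L
    while (pos < n) {
      len <- min(stats::rgeom(1, 1 / cfg$block_mean_bins) + 1L, n - pos)
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom = gc_$chrom[k], start_bin = pos, end_bin = pos + len,
        label1 = lab, stringsAsFactors = FALSE)
      label1 <- c(label1, rep(lab, len))
      pos <- pos + len
      lab <- -lab
    }
  }
  blocks <- do.call(rbind, blocks)
  n_blk <- nrow(blocks)
  n_flip <- round(cfg$f_switch * n_blk)
  flip_idx <- if (n_flip > 0) sample(n_blk, n_flip) else integer(0)
  blocks$flipped <- seq_len(n_blk) %in% flip_idx
  blocks$label2 <- ifelse(blocks$flipped, -blocks$label1, blocks$label1)
  label2 <- rep(blocks$label2, blocks$end_bin - blocks$start_bin)
  blocks$gstart <- gc_$offset[match(blocks$chrom, gc_$chrom)] + blocks$start_bin

  g <- cfg$genome
  b1 <- list(); deleted <- list()
  for (k in seq_along(g$chrom)) {
    n <- g$n_bins[k]
    pos_bins <- seq(cfg$tad_offset_bins, n - 1, by = cfg$tad_spacing_bins)
    pos_bins <- pos_bins[pos_bins > 0 & pos_bins < n - 1]
    bp <- pos_bins * g$bin_size
    b1[[k]] <- data.frame(chrom = g$chrom[k], pos = bp,
                          stringsAsFactors = FALSE)
  }
  b1 <- do.call(rbind, b1)
  n_del <- round(cfg$f_loss * nrow(b1))
  del_idx <- if (n_del > 0) sample(nrow(b1), n_del) else integer(0)
  b1$deleted <- seq_len(nrow(b1)) %in% del_idx
  structure(list(
    label1 = label1, label2 = label2, blocks = blocks,
    boundaries1 = b1[, c("chrom", "pos")],
    boundaries2 = b1[!b1$deleted, c("chrom", "pos")],
    deleted_boundaries = b1[b1$deleted, c("chrom", "pos")],
    boundary_table = b1
  ), class = "truth_tables")
}

# per-bin compartment sign at the Hi-C resolution, for one condition
truth_sign_hic <- function(cfg, truth, condition) {
  lab <- if (condition == 1) truth$label1 else truth$label2
  ratio <- as.integer(cfg$compartment_bin / cfg$bin_size)
  g <- cfg$genome; gc_ <- cfg$genome_comp
  s <- integer(g$total_bins)
  for (k in seq_along(g$chrom)) {
    comp_lab <- lab[(gc_$offset[k] + 1):(gc_$offset[k] + gc_$n_bins[k])]
    expanded <- rep(comp_lab, each = ratio)[seq_len(g$n_bins[k])]
    s[(g$offset[k] + 1):(g$offset[k] + g$n_bins[k])] <- expanded
  }
  s
}

# TAD domain id per hic bin for one condition (0 = none; ids unique per chrom)
truth_tad_id <- function(cfg, truth, condition) {
  b <- if (condition == 1) truth$boundaries1 else truth$boundaries2
  g <- cfg$genome
  id <- integer(g$total_bins)
  next_id <- 1L
  for (k in seq_along(g$chrom)) {
    bp <- sort(b$pos[b$chrom == g$chrom[k]])
    edges <- c(0, bp, g$length[k])
    bins <- seq_len(g$n_bins[k]) - 1L
    starts <- bins * g$bin_size
    dom <- findInterval(starts, edges, rightmost.closed = FALSE)
    id[(g$offset[k] + 1):(g$offset[k] + g$n_bins[k])] <- next_id + dom - 1L
    next_id <- next_id + length(edges) - 1L
  }
  id
}

#' Simulate a condition's Hi-C contact matrix
#'
#' @param cfg a [sim_config()].
#' @param condition 1 (control) or 2 (stress).
#' @param truth a [simulate_truth()] result; generated from `cfg` when
#'   missing (so the same truth can be shared across conditions).
#' @return list with `matrix` (a [contact_matrix()] at `cfg$bin_size`) and
#'   `truth`.
#' @export
simulate_hic <- function(cfg, condition, truth = NULL) {
  stopifnot(condition %in% c(1, 2))
  if (is.null(truth)) truth <- simulate_truth(cfg)
  g <- cfg$genome
  s <- truth_sign_hic(cfg, truth, condition)
  tad <- truth_tad_id(cfg, truth, condition)
  alpha <- cfg$alpha[condition]

  # per-chromosome weights; two passes (total weight, then draw)
  chrom_pairs <- function(k) {
    n <- g$n_bins[k]; off <- g$offset[k]
    i <- rep.int(seq_len(n), times = n - seq_len(n) + 1L)
    j <- sequence(n - seq_len(n) + 1L) + i - 1L
    d <- pmax(j - i, 1L)
    w <- d^(-alpha) *
      (1 + cfg$c_strength * s[off + i] * s[off + j]) *
      ifelse(tad[off + i] == tad[off + j], cfg$tau, 1)
    list(i = off + i - 1L, j = off + j - 1L, w = w)
  }
  total_w <- 0
  for (k in seq_along(g$chrom)) total_w <- total_w + sum(chrom_pairs(k)$w)

  set.seed(cfg$seed * 131L + condition)
  ii <- list(); jj <- list(); cc <- list()
  for (k in seq_along(g$chrom)) {
    p <- chrom_pairs(k)
    lam <- cfg$depth * p$w / total_w
    cnt <- stats::rpois(length(lam), lam)
    keep <- cnt > 0
    ii[[k]] <- p$i[keep]; jj[[k]] <- p$j[keep]; cc[[k]] <- cnt[keep]
  }
  # trans background: constant-rate Poisson field, drawn as a total count
  # scattered uniformly over inter-chromosomal bin pairs
  if (cfg$trans_rate > 0 && length(g$chrom) > 1) {
    nb <- g$n_bins
    n_trans_pairs <- (sum(nb)^2 - sum(nb^2)) / 2
    n_reads <- stats::rpois(1, cfg$depth * cfg$trans_rate * n_trans_pairs)
    if (n_reads > 0) {
      # rejection-free: draw global pairs until chroms differ
      ti <- integer(0); tj <- integer(0)
      while (length(ti) < n_reads) {
        need <- n_reads - length(ti)
        a <- sample.int(g$total_bins, need * 2, replace = TRUE) - 1L
        b <- sample.int(g$total_bins, need * 2, replace = TRUE) - 1L
        ca <- findInterval(a, g$offset); cb <- findInterval(b, g$offset)
        ok <- ca != cb
        ti <- c(ti, pmin(a[ok], b[ok])); tj <- c(tj, pmax(a[ok], b[ok]))
      }
      ti <- ti[seq_len(n_reads)]; tj <- tj[seq_len(n_reads)]
      ii[[length(ii) + 1L]] <- ti
      jj[[length(jj) + 1L]] <- tj
      cc[[length(cc) + 1L]] <- rep(1, n_reads)
    }
  }
  m <- contact_matrix(g, unlist(ii), unlist(jj), unlist(cc))
  list(matrix = m, truth = truth)
}

#' Place genes and TEs on the simulated genome
#'
#' Genes are enriched in A blocks (odds `gene_density_ratio` : 1) and TEs
#' in B blocks (reciprocal), so the A compartment is gene-rich as the
#' sign-orientation rule for compartment calling requires.
#'
#' @param cfg a [sim_config()].
#' @param truth a [simulate_truth()] result.
#' @return list with `genes` and `tes` interval tables (sorted).
#' @export
simulate_features <- function(cfg, truth) {
  set.seed(cfg$seed * 131L + 11L)
  gc_ <- cfg$genome_comp
  place <- function(n, weights, len_range, kind) {
    bin <- sample.int(gc_$total_bins, n, replace = TRUE,
                      prob = weights / sum(weights))
    bt <- bin_table(bin - 1L, gc_)
    len <- round(stats::runif(n, len_range[1], len_range[2]))
    start <- bt$start + floor(stats::runif(n) * pmax(bt$end - bt$start - len, 1))
    start <- pmax(start, 0)
    end <- pmin(start + len, gc_$length[match(bt$chrom, gc_$chrom)])
    strand <- sample(c("+", "-"), n, replace = TRUE)
    iv <- intervals(bt$chrom, start, end, strand = strand, kind = kind)
    iv <- iv[order(match(iv$chrom, gc_$chrom), iv$start), ]
    iv$id <- sprintf("%s_%05d", kind, seq_len(n))
    rownames(iv) <- NULL
    class(iv) <- c("intervals", "data.frame")
    iv
  }
  wA <- ifelse(truth$label1 > 0, cfg$gene_density_ratio, 1)
  wB <- ifelse(truth$label1 < 0, cfg$gene_density_ratio, 1)
  list(genes = place(cfg$n_genes, wA, c(1000, 5000), "gene"),
       tes = place(cfg$n_tes, wB, c(300, 3000), "TE"))
}

# planted log2FC per feature given truth (direction of the block flip at
# the feature midpoint; TAD-shared and gene-level noise added)
planted_l2fc <- function(cfg, truth, features, effect) {
  mid_bin <- bin_of(features$chrom, midpoints(features), cfg$genome_comp) + 1L
  dir <- ifelse(truth$label1[mid_bin] < 0 & truth$label2[mid_bin] > 0, 1,
         ifelse(truth$label1[mid_bin] > 0 & truth$label2[mid_bin] < 0, -1, 0))
  tad_id <- truth_tad_id(cfg, truth, 1)
  mid_hic <- bin_of(features$chrom, midpoints(features), cfg$genome) + 1L
  f_tad <- tad_id[mid_hic]
  tad_eff <- stats::rnorm(max(f_tad), 0, cfg$sigma_tad)
  effect * dir + tad_eff[f_tad] + stats::rnorm(nrow(features), 0, cfg$gene_noise_sd)
}

#' Simulate a replicated expression count table with planted effects
#'
#' Condition-2 means are condition-1 means scaled by `2^log2FC`, where the
#' planted log2FC is `beta` times the switch direction at the feature
#' midpoint (+ for B->A, - for A->B), plus a TAD-shared Normal(0,
#' sigma_tad) component and gene-level Normal(0, gene_noise_sd) noise.
#' Replicate counts are log-normal-Poisson around the condition mean.
#'
#' @param cfg a [sim_config()].
#' @param truth a [simulate_truth()] result.
#' @param features interval table of genes (or TEs).
#' @return list: `counts` (a [count_table()], conditions "cond1"/"cond2"),
#'   `true_l2fc`, `true_de` (|log2FC| >= 1).
#' @export
simulate_expression <- function(cfg, truth, features) {
  set.seed(cfg$seed * 131L + 23L)
  n <- nrow(features)
  base <- stats::rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
  base <- base * cfg$rna_depth / sum(base)
  l2fc <- planted_l2fc(cfg, truth, features, cfg$beta)
  mu2 <- base * 2^l2fc
  mu2 <- mu2 * cfg$rna_depth / sum(mu2)
  draw_reps <- function(mu, n_reps) {
    vapply(seq_len(n_reps), function(r) {
      noise <- exp(stats::rnorm(n, 0, cfg$rep_disp) - cfg$rep_disp^2 / 2)
      stats::rpois(n, mu * noise)
    }, numeric(n))
  }
  counts <- cbind(draw_reps(base, cfg$n_reps_rna),
                  draw_reps(mu2, cfg$n_reps_rna))
  rownames(counts) <- features$id
  colnames(counts) <- c(paste0("cond1_rep", seq_len(cfg$n_reps_rna)),
                        paste0("cond2_rep", seq_len(cfg$n_reps_rna)))
  cond <- rep(c("cond1", "cond2"), each = cfg$n_reps_rna)
  list(counts = count_table(counts, cond),
       true_l2fc = stats::setNames(l2fc, features$id),
       true_de = stats::setNames(abs(l2fc) >= 1, features$id))
}

#' Simulate ATAC peaks and a replicated peak count table
#'
#' Peaks sit at the TSS of a random subset of genes plus an intergenic
#' background; intensity is elevated in A-compartment bins. A peak whose
#' midpoint lies in a flipped compartment block is truly differential
#' with probability `coupling_prob`; differential peaks shift their
#' condition-2 mean by `2^(atac_shift_log2)` in the switch direction.
#'
#' @param cfg a [sim_config()].
#' @param truth a [simulate_truth()] result.
#' @param genes gene interval table (TSS source).
#' @return list: `peaks` (intervals), `counts` (a [count_table()]),
#'   `true_diff` (logical per peak), `true_dir` (+1/-1/0).
#' @export
simulate_atac <- function(cfg, truth, genes) {
  set.seed(cfg$seed * 131L + 37L)
  g <- cfg$genome
  n_tss <- round(cfg$peak_frac_genes * nrow(genes))
  tss_genes <- genes[sort(sample(nrow(genes), n_tss)), ]
  tss <- ifelse(tss_genes$strand == "-", tss_genes$end - 1, tss_genes$start)
  half <- cfg$peak_width / 2
  p_start <- pmax(tss - half, 0)
  p_end <- pmin(tss + half, g$length[match(tss_genes$chrom, g$chrom)])
  bg_chrom_i <- sample.int(length(g$chrom), cfg$n_bg_peaks, replace = TRUE)
  bg_start <- floor(stats::runif(cfg$n_bg_peaks) *
                      (g$length[bg_chrom_i] - cfg$peak_width))
  peaks <- intervals(
    c(tss_genes$chrom, g$chrom[bg_chrom_i]),
    c(p_start, bg_start),
    c(p_end, bg_start + cfg$peak_width),
    kind = "peak")
  ord <- order(match(peaks$chrom, g$chrom), peaks$start)
  peaks <- peaks[ord, ]
  peaks$id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  rownames(peaks) <- NULL
  class(peaks) <- c("intervals", "data.frame")

  n <- nrow(peaks)
  mid_bin <- bin_of(peaks$chrom, midpoints(peaks), cfg$genome_comp) + 1L
  in_A <- truth$label1[mid_bin] > 0
  base <- stats::rlnorm(n, cfg$atac_meanlog, cfg$atac_sdlog) *
    ifelse(in_A, cfg$atac_a_boost, 1)
  base <- base * cfg$atac_depth / sum(base)
  dir <- ifelse(truth$label1[mid_bin] < 0 & truth$label2[mid_bin] > 0, 1,
         ifelse(truth$label1[mid_bin] > 0 & truth$label2[mid_bin] < 0, -1, 0))
  flagged <- dir != 0 & stats::runif(n) < cfg$coupling_prob
  shift <- ifelse(flagged, dir * cfg$atac_shift_log2, 0)
  mu2 <- base * 2^shift
  draw_reps <- function(mu, n_reps) {
    vapply(seq_len(n_reps), function(r) {
      noise <- exp(stats::rnorm(n, 0, cfg$rep_disp) - cfg$rep_disp^2 / 2)
      stats::rpois(n, mu * noise)
    }, numeric(n))
  }
  counts <- cbind(draw_reps(base, cfg$n_reps_atac),
                  draw_reps(mu2, cfg$n_reps_atac))
  rownames(counts) <- peaks$id
  colnames(counts) <- c(paste0("cond1_rep", seq_len(cfg$n_reps_atac)),
                        paste0("cond2_rep", seq_len(cfg$n_reps_atac)))
  cond <- rep(c("cond1", "cond2"), each = cfg$n_reps_atac)
  list(peaks = peaks,
       counts = count_table(counts, cond),
       true_diff = stats::setNames(flagged, peaks$id),
       true_dir = stats::setNames(dir, peaks$id))
}

#' Generate the full simulated multi-omic bundle
#'
#' Runs truth, Hi-C (both conditions, with a 100-kb aggregation),
#' feature placement, expression (genes and TEs) and ATAC, optionally
#' writing every table to `dir` through the package writers.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; created if needed.
#' @return list with all simulated objects and the truth tables.
#' @export
simulate_bundle <- function(cfg, dir = NULL) {
  truth <- simulate_truth(cfg)
  hic1 <- simulate_hic(cfg, 1, truth)
  hic2 <- simulate_hic(cfg, 2, truth)
  feats <- simulate_features(cfg, truth)
  rna <- simulate_expression(cfg, truth, feats$genes)
  te_rna <- simulate_expression(cfg, truth, feats$tes)
  atac <- simulate_atac(cfg, truth, feats$genes)
  bundle <- list(
    cfg = cfg, truth = truth,
    hic = list(hic1$matrix, hic2$matrix),
    hic_comp = list(aggregate_matrix(hic1$matrix, cfg$compartment_bin),
                    aggregate_matrix(hic2$matrix, cfg$compartment_bin)),
    genes = feats$genes, tes = feats$tes,
    rna = rna, te_rna = te_rna, atac = atac)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix(bundle$hic[[1]], file.path(dir, "cond1_5kb"))
    write_matrix(bundle$hic[[2]], file.path(dir, "cond2_5kb"))
    write_matrix(bundle$hic_comp[[1]], file.path(dir, "cond1_100kb"))
    write_matrix(bundle$hic_comp[[2]], file.path(dir, "cond2_100kb"))
    write_intervals(bundle$genes, file.path(dir, "genes.bed"))
    write_intervals(bundle$tes, file.path(dir, "tes.bed"))
    write_intervals(bundle$atac$peaks, file.path(dir, "peaks.bed"))
    write_counts(bundle$rna$counts, file.path(dir, "rna_counts.tsv"))
    write_counts(bundle$te_rna$counts, file.path(dir, "te_counts.tsv"))
    write_counts(bundle$atac$counts, file.path(dir, "atac_counts.tsv"))
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    utils::write.table(truth$blocks, file.path(tdir, "blocks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$boundary_table,
                       file.path(tdir, "boundaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(id = names(rna$true_l2fc), true_l2fc = rna$true_l2fc,
                 true_de = rna$true_de),
      file.path(tdir, "gene_effects.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(id = names(atac$true_diff), true_diff = atac$true_diff,
                 true_dir = atac$true_dir),
      file.path(tdir, "peak_effects.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bundle
}
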