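# Accessibility-track statistics: strand-aware metagene profiles with
# fixed flanks and a length-scaled body, a differential-peak test,
# peak feature classification, Fisher association with switch regions,
# boundary-loss peak counts and a circular-shift permutation test for
# interval overlap enrichment.

#' Per-condition peak signal (counts-per-million coverage)
#'
#' Converts a replicated peak count table into per-condition mean CPM
#' per peak, the normalized signal used by [metagene_profile()].
#'
#' @param peaks peak interval table.
#' @param counts a [count_table()] with rownames matching `peaks$id`.
#' @return list: `peaks`, `cpm` (matrix peaks x conditions),
#'   `conditions`.
#' @export
peak_signal <- function(peaks, counts) {
  cm <- counts$counts[peaks$id, , drop = FALSE]
  cpm <- sweep(cm, 2, colSums(counts$counts) / 1e6, "/")
  conds <- unique(counts$condition)
  by_cond <- vapply(conds, function(cd)
    rowMeans(cpm[, counts$condition == cd, drop = FALSE]), numeric(nrow(cm)))
  list(peaks = peaks, cpm = by_cond, conditions = conds)
}

# per-chromosome weighted coverage (Rle list) from peaks + one value col
peak_coverage <- function(peaks, values, genome) {
  gr <- GenomicRanges::GRanges(
    factor(peaks$chrom, levels = genome$chrom),
    IRanges::IRanges(peaks$start + 1, peaks$end))
  GenomicRanges::coverage(gr, weight = values,
                          width = stats::setNames(as.list(genome$length),
                                                  genome$chrom))
}

# value of an RleList coverage at 1-based positions on given chroms
coverage_at <- function(cvg, chrom, pos1) {
  out <- numeric(length(pos1))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    out[sel] <- as.numeric(cvg[[ch]][pos1[sel]])
  }
  out
}

#' Strand-aware metagene profile of accessibility signal
#'
#' Signal is averaged over features on a common relative grid: fixed-bp
#' flanks sampled at `flank_bins` points each side, and the feature body
#' scaled into `body_bins` points. Minus-strand features are reversed.
#' Strata (e.g. compartment class of the feature) yield separate curves;
#' a two-sided Mann-Whitney test compares per-feature mean signal
#' between the two conditions within each stratum.
#'
#' @param signal a [peak_signal()] result (peaks + per-condition CPM).
#' @param features feature intervals (genes, switch segments, TADs ...).
#' @param genome a [genome_spec()].
#' @param flank flank width in bp (default 1000).
#' @param body_bins grid points across the feature body (default 20).
#' @param flank_bins grid points per flank (default 10).
#' @param strata optional per-feature labels; NA features are dropped.
#' @return list of class `meta_profile`: `profile` (long data.frame:
#'   stratum, position, rel_pos, condition, mean, n) and `tests`
#'   (per-stratum Mann-Whitney p between conditions).
#' @export
metagene_profile <- function(signal, features, genome, flank = 1000,
                             body_bins = 20, flank_bins = 10,
                             strata = NULL) {
  stopifnot(flank > 0, body_bins > 0, flank_bins > 0)
  if (!nrow(features)) stop("empty feature set")
  if (is.null(strata)) strata <- rep("all", nrow(features))
  keep <- !is.na(strata)
  features <- features[keep, , drop = FALSE]
  strata <- strata[keep]
  n_grid <- 2 * flank_bins + body_bins
  conds <- signal$conditions
  cvg <- lapply(seq_along(conds), function(ci)
    peak_coverage(signal$peaks, signal$cpm[, ci], genome))
  # genomic coordinate of each grid point for each feature (strand-aware;
  # matrix n_features x n_grid)
  nf <- nrow(features)
  up_off <- seq(-flank, -flank / flank_bins, length.out = flank_bins)
  down_off <- seq(flank / flank_bins, flank, length.out = flank_bins)
  body_frac <- (seq_len(body_bins) - 0.5) / body_bins
  # build the plus-orientation grid with its right half defined as the
  # discrete mirror (x -> start + end - 1 - x) of the left half, then
  # reflect minus-strand rows in place; strand reversal then reverses
  # the profile exactly
  pos <- matrix(0, nf, n_grid)
  len <- features$end - features$start
  half <- ceiling(n_grid / 2)
  for (gi in seq_len(min(flank_bins, half)))
    pos[, gi] <- features$start + round(up_off[gi])
  for (gi in seq_len(max(half - flank_bins, 0)))
    pos[, flank_bins + gi] <- features$start + round(len * body_frac[gi])
  for (gi in (half + 1):n_grid)
    pos[, gi] <- features$start + features$end - 1 - pos[, n_grid + 1 - gi]
  minus <- which(features$strand == "-")
  if (length(minus))
    pos[minus, ] <- (features$start[minus] + features$end[minus] - 1) -
      pos[minus, , drop = FALSE]
  chrom_len <- genome$length[match(features$chrom, genome$chrom)]
  pos <- pmax(pmin(round(pos), chrom_len - 1), 0)
  rel <- c(up_off, paste0("body", seq_len(body_bins)), down_off)
  # per-feature per-grid signal per condition
  vals <- lapply(seq_along(conds), function(ci) {
    v <- matrix(0, nf, n_grid)
    for (gi in seq_len(n_grid)) {
      v[, gi] <- coverage_at(cvg[[ci]], features$chrom, pos[, gi] + 1)
    }
    v
  })
  prof <- list(); tests <- list()
  for (st in unique(strata)) {
    sel <- strata == st
    for (ci in seq_along(conds)) {
      prof[[length(prof) + 1L]] <- data.frame(
        stratum = st, position = seq_len(n_grid), rel_pos = rel,
        condition = conds[ci],
        mean = colMeans(vals[[ci]][sel, , drop = FALSE]),
        n = sum(sel), stringsAsFactors = FALSE)
    }
    if (length(conds) >= 2) {
      a <- rowMeans(vals[[1]][sel, , drop = FALSE])
      b <- rowMeans(vals[[2]][sel, , drop = FALSE])
      p <- if (sum(sel) > 0)
        suppressWarnings(stats::wilcox.test(a, b)$p.value) else NA_real_
      tests[[length(tests) + 1L]] <- data.frame(
        stratum = st, n = sum(sel), pvalue = p, stringsAsFactors = FALSE)
    }
  }
  structure(list(profile = do.call(rbind, prof),
                 tests = if (length(tests)) do.call(rbind, tests) else NULL,
                 flank = flank, body_bins = body_bins,
                 flank_bins = flank_bins),
            class = "meta_profile")
}

#' Differential accessibility peaks
#'
#' Applies the same Welch-on-log statistical engine as
#' [differential_expression()] to per-peak counts, with peak widths as
#' feature lengths; a peak is differential when its BH-adjusted p-value
#' falls below `p_threshold` (no fold-change cutoff). An externally
#' produced differential-peak id set can bypass the test.
#'
#' @param counts a [count_table()] over peaks.
#' @param peaks optional peak intervals (for widths; 1 kb assumed
#'   otherwise).
#' @param p_threshold adjusted-p cutoff (default 0.05).
#' @param external optional character vector of differential peak ids;
#'   when given, flags are taken verbatim and no test is run.
#' @return data.frame of class `peak_stats`: `feature_id`, `log2fc`,
#'   `pvalue`, `padj`, `differential`.
#' @export
differential_peaks <- function(counts, peaks = NULL, p_threshold = 0.05,
                               external = NULL) {
  ids <- rownames(counts$counts)
  if (!is.null(external)) {
    out <- data.frame(feature_id = ids, log2fc = NA_real_,
                      pvalue = NA_real_, padj = NA_real_,
                      differential = ids %in% external,
                      stringsAsFactors = FALSE)
    class(out) <- c("peak_stats", "data.frame")
    return(out)
  }
  lengths <- if (!is.null(peaks))
    stats::setNames(peaks$end - peaks$start, peaks$id)[ids]
  else stats::setNames(rep(1000, length(ids)), ids)
  de <- differential_expression(counts, lengths, lfc_threshold = 0,
                                p_threshold = p_threshold)
  out <- data.frame(feature_id = de$feature_id, log2fc = de$log2fc,
                    pvalue = de$pvalue, padj = de$padj,
                    differential = !is.na(de$padj) & de$padj < p_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_stats", "data.frame")
  out
}

#' Classify peaks as promoter / gene body / intergenic
#'
#' The promoter is the `promoter_bp` window immediately upstream of the
#' TSS on the coding strand; classification is by peak midpoint with
#' precedence promoter > gene body > intergenic.
#'
#' @param peaks peak intervals.
#' @param genes gene intervals (strand used for TSS).
#' @param promoter_bp promoter width in bp (default 1000).
#' @return character vector of classes, one per peak.
#' @export
classify_peak_features <- function(peaks, genes, promoter_bp = 1000) {
  stopifnot(promoter_bp > 0)
  mid <- midpoints(peaks)
  mid_gr <- GenomicRanges::GRanges(peaks$chrom,
                                   IRanges::IRanges(mid + 1, mid + 1))
  tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  prom_start <- ifelse(genes$strand == "-", tss + 1, tss - promoter_bp)
  prom_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(pmax(prom_start, 0) + 1,
                                  pmax(prom_start, 0) + promoter_bp))
  gene_gr <- iv_to_granges(genes)
  cls <- rep("intergenic", nrow(peaks))
  in_gene <- unique(S4Vectors::queryHits(suppressWarnings(
    GenomicRanges::findOverlaps(mid_gr, gene_gr, ignore.strand = TRUE))))
  cls[in_gene] <- "gene_body"
  in_prom <- unique(S4Vectors::queryHits(suppressWarnings(
    GenomicRanges::findOverlaps(mid_gr, prom_gr, ignore.strand = TRUE))))
  cls[in_prom] <- "promoter"
  cls
}

#' Fisher's exact association of differential peaks with regions
#'
#' 2x2 table of {differential, non-differential} x {midpoint inside a
#' region, outside}; two-sided Fisher exact p and the cross-product
#' odds ratio (a*d)/(b*c).
#'
#' @param peaks peak intervals.
#' @param is_diff logical vector, one flag per peak.
#' @param regions interval table (e.g. switch segments).
#' @return object of class `enrichment_result` with `table`, `odds_ratio`,
#'   `pvalue`, `test`, `flagged` (TRUE when a margin is empty).
#' @export
fisher_association <- function(peaks, is_diff, regions) {
  if (!nrow(peaks)) stop("zero peaks")
  mid <- midpoints(peaks)
  in_region <- rep(FALSE, nrow(peaks))
  if (nrow(regions)) {
    mid_gr <- GenomicRanges::GRanges(peaks$chrom,
                                     IRanges::IRanges(mid + 1, mid + 1))
    reg_gr <- GenomicRanges::GRanges(
      regions$chrom, IRanges::IRanges(regions$start + 1, regions$end))
    hit <- GenomicRanges::findOverlaps(mid_gr, reg_gr, ignore.strand = TRUE)
    in_region[unique(S4Vectors::queryHits(hit))] <- TRUE
  }
  a <- sum(is_diff & in_region); b <- sum(is_diff & !in_region)
  c_ <- sum(!is_diff & in_region); d <- sum(!is_diff & !in_region)
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(c("diff", "nondiff"), c("in", "out")))
  flagged <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (flagged) NA_real_ else stats::fisher.test(tab)$p.value
  or <- if (b * c_ == 0) {
    if (a * d > 0) Inf else NA_real_
  } else (a * d) / (b * c_)
  structure(list(table = tab, odds_ratio = or, pvalue = p,
                 test = "fisher_exact_two_sided", flagged = flagged),
            class = "enrichment_result")
}

#' Differential peak load in domains with vs without boundary loss
#'
#' @param peaks peak intervals.
#' @param is_diff logical differential flags per peak.
#' @param domains_with_loss,domains_without disjoint interval tables.
#' @return data.frame: one row per group with `n_domains`, `total_bp`,
#'   `n_diff_peaks`, `rate_per_kb`, `flagged` (TRUE when the group has
#'   no domains).
#' @export
boundary_loss_peak_counts <- function(peaks, is_diff, domains_with_loss,
                                      domains_without) {
  if (nrow(domains_with_loss) && nrow(domains_without)) {
    g1 <- GenomicRanges::GRanges(domains_with_loss$chrom,
            IRanges::IRanges(domains_with_loss$start + 1,
                             domains_with_loss$end))
    g2 <- GenomicRanges::GRanges(domains_without$chrom,
            IRanges::IRanges(domains_without$start + 1, domains_without$end))
    if (length(GenomicRanges::findOverlaps(g1, g2)) > 0)
      stop("overlapping domain sets")
  }
  mid <- midpoints(peaks[is_diff, , drop = FALSE])
  chrom <- peaks$chrom[is_diff]
  count_in <- function(doms) {
    if (!nrow(doms) || !length(mid)) return(0L)
    mg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(mid + 1, mid + 1))
    dg <- GenomicRanges::GRanges(doms$chrom,
            IRanges::IRanges(doms$start + 1, doms$end))
    length(unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(mg, dg))))
  }
  row_of <- function(name, doms) {
    bp <- sum(doms$end - doms$start)
    nd <- count_in(doms)
    data.frame(group = name, n_domains = nrow(doms), total_bp = bp,
               n_diff_peaks = nd,
               rate_per_kb = if (bp > 0) nd / (bp / 1e3) else NA_real_,
               flagged = nrow(doms) == 0, stringsAsFactors = FALSE)
  }
  rbind(row_of("with_loss", domains_with_loss),
        row_of("without_loss", domains_without))
}

#' Interval overlap enrichment by circular-shift permutation
#'
#' Observed statistic: the number of `set1` intervals overlapping
#' `set2` by >= 1 bp. The null preserves lengths and spacings by
#' circularly shifting all `set1` intervals on each chromosome by an
#' independent uniform offset per permutation (wrap-around intervals are
#' split). Empirical p = (1 + #{null >= observed}) / (1 + n_perm).
#'
#' @param set1,set2 interval tables on one genome.
#' @param genome a [genome_spec()].
#' @param n_perm number of permutations (default 500).
#' @param seed RNG seed.
#' @return object of class `enrichment_result` with `observed`,
#'   `null_mean`, `null_sd`, `n_perm`, `pvalue`.
#' @export
interval_overlap_enrichment <- function(set1, set2, genome, n_perm = 500,
                                        seed = 1) {
  if (!nrow(set1) || !nrow(set2)) stop("empty interval set")
  stopifnot(n_perm >= 1)
  set.seed(seed)
  gr2 <- GenomicRanges::reduce(GenomicRanges::GRanges(
    set2$chrom, IRanges::IRanges(set2$start + 1, set2$end)))
  count_overlap <- function(chrom, start, end) {
    gr1 <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
    sum(IRanges::overlapsAny(gr1, gr2, ignore.strand = TRUE))
  }
  observed <- count_overlap(set1$chrom, set1$start, set1$end)
  len <- genome$length[match(set1$chrom, genome$chrom)]
  null <- vapply(seq_len(n_perm), function(p) {
    shift <- stats::setNames(
      floor(stats::runif(length(genome$chrom)) * genome$length),
      genome$chrom)
    s <- (set1$start + shift[set1$chrom]) %% len
    e <- s + (set1$end - set1$start)
    wrap <- e > len
    # wrapped intervals: count as overlapping if either piece overlaps
    gr_main <- GenomicRanges::GRanges(
      set1$chrom, IRanges::IRanges(s + 1, pmin(e, len)))
    hit <- IRanges::overlapsAny(gr_main, gr2, ignore.strand = TRUE)
    if (any(wrap)) {
      gr_tail <- GenomicRanges::GRanges(
        set1$chrom[wrap], IRanges::IRanges(1, e[wrap] - len[wrap]))
      hit[wrap] <- hit[wrap] |
        IRanges::overlapsAny(gr_tail, gr2, ignore.strand = TRUE)
    }
    sum(hit)
  }, numeric(1))
  structure(list(observed = observed, null_mean = mean(null),
                 null_sd = stats::sd(null), n_perm = n_perm,
                 pvalue = (1 + sum(null >= observed)) / (1 + n_perm),
                 test = "circular_shift_permutation"),
            class = "enrichment_result")
}

#' Expression split by ATAC peak presence at promoter or gene body
#'
#' Genes are split by whether any peak midpoint falls in their promoter
#' (strand-aware upstream window) or gene body; mean FPKM per group is
#' compared with a two-sided Mann-Whitney test.
#'
#' @param stats an `expression_stats` table (with the FPKM attribute).
#' @param peaks peak intervals.
#' @param genes gene intervals.
#' @param promoter_bp promoter width in bp (default 1000).
#' @return list: `with_peak`, `without_peak` (mean-FPKM vectors),
#'   `pvalue`, `flagged` (TRUE when a group is empty).
#' @export
expression_by_peak_presence <- function(stats, peaks, genes,
                                        promoter_bp = 1000) {
  fk <- attr(stats, "fpkm")
  mean_fpkm <- if (!is.null(fk)) rowMeans(fk) else
    stats::setNames((stats$mean_fpkm1 + stats$mean_fpkm2) / 2,
                    stats$feature_id)
  mid <- midpoints(peaks)
  mid_gr <- GenomicRanges::GRanges(peaks$chrom,
                                   IRanges::IRanges(mid + 1, mid + 1))
  tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  reg_start <- ifelse(genes$strand == "-", genes$start,
                      pmax(tss - promoter_bp, 0))
  reg_end <- ifelse(genes$strand == "-",
                    pmin(tss + 1 + promoter_bp, Inf), genes$end)
  reg_end <- pmax(reg_end, reg_start + 1)
  reg_gr <- GenomicRanges::GRanges(genes$chrom,
              IRanges::IRanges(reg_start + 1, reg_end))
  hit <- GenomicRanges::findOverlaps(mid_gr, reg_gr, ignore.strand = TRUE)
  has_peak <- seq_len(nrow(genes)) %in% S4Vectors::subjectHits(hit)
  fpkm_of <- mean_fpkm[match(genes$id, stats$feature_id)]
  ok <- !is.na(fpkm_of)
  w <- fpkm_of[ok & has_peak]; wo <- fpkm_of[ok & !has_peak]
  flagged <- !length(w) || !length(wo)
  p <- if (flagged) NA_real_ else
    suppressWarnings(stats::wilcox.test(w, wo)$p.value)
  list(with_peak = w, without_peak = wo, pvalue = p, flagged = flagged)
}
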