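# Expression summaries and expression-architecture statistics: FPKM,
# fold changes with a Welch-on-log-FPKM differential test, switch-region
# expression shifts, and within-TAD co-regulation against size-matched
# random gene sets.

#' FPKM normalization
#'
#' FPKM = count / ((length / 1e3) * (library_total / 1e6)), with library
#' totals taken as the column sums of the count table.
#'
#' @param counts a [count_table()].
#' @param lengths named numeric vector of feature lengths in bp (matched
#'   to rownames of the counts).
#' @return matrix of FPKM values, features x samples.
#' @export
fpkm <- function(counts, lengths) {
  cm <- counts$counts
  len <- lengths[rownames(cm)]
  if (anyNA(len)) stop("missing length for some features")
  if (any(len <= 0)) stop("feature lengths must be > 0")
  lib <- colSums(cm)
  if (any(lib == 0)) stop("zero library size")
  sweep(cm / (len / 1e3), 2, lib / 1e6, "/")
}

#' Differential expression (moderated t on log2 FPKM)
#'
#' A deliberately simple two-condition test: log2 fold change of mean
#' FPKM (with a pseudocount), and a two-sided moderated t-test
#' (limma's empirical-Bayes variance shrinkage) on
#' log2(FPKM + pseudocount) per feature, BH-adjusted across features.
#' Variance moderation borrows strength across features, which is what
#' makes 2-3 replicates per condition workable; a plain per-feature
#' Welch test has essentially no power at that design. This is not a
#' negative-binomial GLM; externally computed tables (e.g. from DESeq2)
#' can be substituted via [external_expression_stats()].
#'
#' @param counts a [count_table()] with >= 2 replicates per condition.
#' @param lengths named feature lengths in bp.
#' @param pseudocount added to FPKM before logs (default 1).
#' @param lfc_threshold |log2FC| cutoff for the DE flag (default 1).
#' @param p_threshold adjusted-p cutoff for the DE flag (default 0.01).
#' @param conditions the two condition labels to compare, in order
#'   (reference first); defaults to the order of first appearance.
#' @return data.frame of class `expression_stats`: `feature_id`,
#'   `mean_fpkm1`, `mean_fpkm2`, `log2fc`, `pvalue`, `padj`, `de`;
#'   the full FPKM matrix is attached as attribute `"fpkm"`.
#' @export
differential_expression <- function(counts, lengths, pseudocount = 1,
                                    lfc_threshold = 1, p_threshold = 0.01,
                                    conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(counts$condition)[1:2]
  s1 <- which(counts$condition == conditions[1])
  s2 <- which(counts$condition == conditions[2])
  fk <- fpkm(counts, lengths)
  m1 <- rowMeans(fk[, s1, drop = FALSE])
  m2 <- rowMeans(fk[, s2, drop = FALSE])
  l2fc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  have_p <- length(s1) >= 2 && length(s2) >= 2
  pv <- rep(NA_real_, nrow(fk))
  if (have_p) {
    lf <- log2(fk[, c(s1, s2), drop = FALSE] + pseudocount)
    grp <- rep(0:1, c(length(s1), length(s2)))
    design <- stats::model.matrix(~grp)
    fit <- limma::eBayes(limma::lmFit(lf, design))
    pv <- fit$p.value[, 2]
  }
  padj <- stats::p.adjust(pv, method = "BH")
  out <- data.frame(
    feature_id = rownames(fk), mean_fpkm1 = m1, mean_fpkm2 = m2,
    log2fc = l2fc, pvalue = pv, padj = padj,
    de = !is.na(padj) & abs(l2fc) >= lfc_threshold & padj < p_threshold,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fpkm") <- fk
  class(out) <- c("expression_stats", "data.frame")
  out
}

#' Wrap an externally computed differential table
#'
#' Accepts a table of per-feature log2 fold changes and adjusted
#' p-values produced by other software (e.g. a negative-binomial GLM)
#' and coerces it to the `expression_stats` contract used downstream.
#'
#' @param df data.frame with columns `feature_id`, `log2fc`, `padj`
#'   (optionally `mean_fpkm1`, `mean_fpkm2`, `pvalue`).
#' @param lfc_threshold,p_threshold DE flag cutoffs.
#' @return an `expression_stats` data.frame.
#' @export
external_expression_stats <- function(df, lfc_threshold = 1,
                                      p_threshold = 0.01) {
  stopifnot(all(c("feature_id", "log2fc", "padj") %in% names(df)))
  out <- data.frame(
    feature_id = as.character(df$feature_id),
    mean_fpkm1 = if ("mean_fpkm1" %in% names(df)) df$mean_fpkm1 else NA_real_,
    mean_fpkm2 = if ("mean_fpkm2" %in% names(df)) df$mean_fpkm2 else NA_real_,
    log2fc = df$log2fc,
    pvalue = if ("pvalue" %in% names(df)) df$pvalue else NA_real_,
    padj = df$padj,
    stringsAsFactors = FALSE)
  out$de <- !is.na(out$padj) & abs(out$log2fc) >= lfc_threshold &
    out$padj < p_threshold
  class(out) <- c("expression_stats", "data.frame")
  out
}

#' Expression fold-change shift in compartment-switch regions
#'
#' For each switching class, collects the log2 fold changes of features
#' whose midpoint bin carries that class and compares them against all
#' features (the control) with a two-sided Mann-Whitney test.
#'
#' @param stats an `expression_stats` table.
#' @param switch a [classify_switches()] result.
#' @param features interval table matching `stats$feature_id`.
#' @param classes switching classes to report (default both).
#' @return data.frame: `class`, `n`, `median_l2fc`, `control_median`,
#'   `pvalue`, `flagged` (TRUE when the class is empty); the per-class
#'   fold-change vectors are attached as attribute `"vectors"`.
#' @export
switch_region_shift <- function(stats, switch, features,
                                classes = c("A-B", "B-A")) {
  idx <- match(features$id, stats$feature_id)
  ok <- !is.na(idx) & !is.na(stats$log2fc[idx])
  feats <- features[ok, , drop = FALSE]
  l2fc <- stats$log2fc[idx[ok]]
  cls <- switch_class_at(switch, feats$chrom,
                         pmin(midpoints(feats),
                              switch$genome$length[
                                match(feats$chrom, switch$genome$chrom)] - 1))
  vectors <- list(control = l2fc)
  rows <- lapply(classes, function(cl) {
    v <- l2fc[!is.na(cls) & cls == cl]
    vectors[[cl]] <<- v
    empty <- length(v) == 0
    p <- if (empty) NA_real_ else
      suppressWarnings(stats::wilcox.test(v, l2fc)$p.value)
    data.frame(class = cl, n = length(v),
               median_l2fc = if (empty) NA_real_ else stats::median(v),
               control_median = stats::median(l2fc),
               pvalue = p, flagged = empty, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "vectors") <- vectors
  out
}

#' Within-TAD co-regulation of expression fold changes
#'
#' For every TAD containing at least `min_genes` genes (midpoint
#' containment), the SD of member log2 fold changes is compared against
#' SDs of size-matched random gene sets (sampled without replacement
#' from all genes with a defined fold change, `n_random` rounds per
#' TAD), with a two-sided Mann-Whitney test of TAD SDs versus the
#' pooled random SDs.
#'
#' @param stats an `expression_stats` table.
#' @param tads a [domains_from_boundaries()] result.
#' @param genes gene interval table.
#' @param min_genes minimum member genes per TAD (default 3).
#' @param n_random randomization rounds per TAD (default 200).
#' @param seed RNG seed (required for reproducibility).
#' @return list of class `coregulation_result`: `tad_sd` (per qualifying
#'   TAD), `random_sd` (pooled), `pvalue`, `n_tads`, `n_random`.
#' @export
tad_coregulation <- function(stats, tads, genes, min_genes = 3,
                             n_random = 200, seed) {
  stopifnot(min_genes >= 2, n_random >= 1)
  set.seed(seed)
  idx <- match(genes$id, stats$feature_id)
  ok <- !is.na(idx) & !is.na(stats$log2fc[idx])
  genes <- genes[ok, , drop = FALSE]
  l2fc <- stats$log2fc[idx[ok]]
  d <- tads$domains
  mid <- midpoints(genes)
  gene_tad <- rep(NA_integer_, nrow(genes))
  for (r in seq_len(nrow(d))) {
    inr <- genes$chrom == d$chrom[r] & mid >= d$start[r] & mid < d$end[r]
    gene_tad[inr] <- r
  }
  sizes <- table(gene_tad)
  qual <- as.integer(names(sizes))[sizes >= min_genes]
  if (!length(qual)) stop("no TAD passes min_genes")
  tad_sd <- vapply(qual, function(t) stats::sd(l2fc[gene_tad == t &
                                                    !is.na(gene_tad)]),
                   numeric(1))
  rand_sd <- unlist(lapply(qual, function(t) {
    k <- sum(gene_tad == t, na.rm = TRUE)
    vapply(seq_len(n_random),
           function(i) stats::sd(l2fc[sample.int(length(l2fc), k)]),
           numeric(1))
  }))
  p <- suppressWarnings(stats::wilcox.test(tad_sd, rand_sd)$p.value)
  structure(list(tad_sd = tad_sd, random_sd = rand_sd, pvalue = p,
                 n_tads = length(qual), n_random = n_random),
            class = "coregulation_result")
}
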