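# Contact partitioning and distance-decay comparison between conditions:
# cis-short / cis-long / trans classes, log-spaced decay-change curves,
# interaction strength by compartment-label pair, and replicate
# correlation.

#' Partition contact mass into cis-short / cis-long / trans classes
#'
#' Each bin pair's count mass is assigned by the pair's separation:
#' trans when the bins lie on different chromosomes, cis-short when the
#' separation `|i - j| * bin_size` is strictly below `threshold`,
#' cis-long otherwise (a separation exactly at the threshold counts as
#' long).
#'
#' @param m a [contact_matrix()].
#' @param threshold separation threshold in bp (default 20 kb).
#' @return object of class `contact_class_summary`: `counts` and
#'   `fractions` named vectors over `cis_short`, `cis_long`, `trans`.
#' @export
classify_contacts <- function(m, threshold = 20000) {
  stopifnot(threshold > 0)
  g <- m$genome
  ci <- findInterval(m$i, g$offset)
  cj <- findInterval(m$j, g$offset)
  trans <- ci != cj
  dist_bp <- (m$j - m$i) * g$bin_size
  cls <- ifelse(trans, "trans",
                ifelse(dist_bp < threshold, "cis_short", "cis_long"))
  counts <- vapply(c("cis_short", "cis_long", "trans"),
                   function(x) sum(m$count[cls == x]), numeric(1))
  total <- sum(counts)
  structure(list(counts = counts,
                 fractions = if (total > 0) counts / total else counts,
                 threshold = threshold),
            class = "contact_class_summary")
}

# number of intra-chromosomal bin pairs at separation d bins (genome-wide)
n_pairs_at_distance <- function(genome, d) {
  vapply(d, function(dd) sum(pmax(genome$n_bins - dd, 0)), numeric(1))
}

#' Distance-decay change curve between two matrices
#'
#' Matrices are depth-normalized to equal total cis count, cis contact
#' mass is binned into log-spaced separation strata, and the per-stratum
#' mean contact (over all bin pairs, zeros included) is compared as
#' `log2(condition2 / condition1)`.
#'
#' @param m1,m2 [contact_matrix()] objects on the same genome/resolution.
#' @param n_bins number of log-spaced distance strata (default 30).
#' @return data.frame of class `decay_curve`: `dist_lo`, `dist_hi` (bp),
#'   `mean1`, `mean2` (normalized mean contact), `log2_ratio`; strata
#'   with zero mass in either condition have NA ratio.
#' @export
decay_change <- function(m1, m2, n_bins = 30) {
  if (!same_genome(m1$genome, m2$genome)) stop("resolution/genome mismatch")
  g <- m1$genome
  cis_part <- function(m) {
    ci <- findInterval(m$i, g$offset); cj <- findInterval(m$j, g$offset)
    sel <- ci == cj & m$j > m$i
    list(d = (m$j[sel] - m$i[sel]) * g$bin_size, count = m$count[sel])
  }
  c1 <- cis_part(m1); c2 <- cis_part(m2)
  s1 <- sum(c1$count); s2 <- sum(c2$count)
  if (s1 == 0 || s2 == 0) stop("a matrix has no cis contacts")
  dmax <- max(g$n_bins - 1) * g$bin_size
  edges <- exp(seq(log(g$bin_size), log(dmax + 1), length.out = n_bins + 1))
  stratum_mean <- function(cp, total) {
    b <- findInterval(cp$d, edges, rightmost.closed = TRUE)
    mass <- numeric(n_bins)
    agg <- rowsum(cp$count, group = b)
    keep <- as.integer(rownames(agg)) >= 1 & as.integer(rownames(agg)) <= n_bins
    mass[as.integer(rownames(agg))[keep]] <- agg[keep, 1]
    # pairs per stratum from the genome geometry (zeros included)
    np <- vapply(seq_len(n_bins), function(s) {
      dlo <- ceiling(edges[s] / g$bin_size)
      dhi <- floor(edges[s + 1] / g$bin_size)
      if (dhi < dlo) 0 else sum(n_pairs_at_distance(g, dlo:dhi))
    }, numeric(1))
    ifelse(np > 0, (mass / total) / np, NA_real_)
  }
  mean1 <- stratum_mean(c1, s1)
  mean2 <- stratum_mean(c2, s2)
  ratio <- ifelse(!is.na(mean1) & !is.na(mean2) & mean1 > 0 & mean2 > 0,
                  log2(mean2 / mean1), NA_real_)
  out <- data.frame(dist_lo = edges[-length(edges)], dist_hi = edges[-1],
                    mean1 = mean1, mean2 = mean2, log2_ratio = ratio)
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Mean O/E interaction strength by compartment-label pair
#'
#' O/E is computed per chromosome against the distance-expected model;
#' off-diagonal intra-chromosomal bin pairs are grouped by the label
#' pair of their bins (A-A, B-B, A-B) and averaged. NA-labeled bins are
#' excluded.
#'
#' @param m a [contact_matrix()] at the profile's resolution.
#' @param profile a [call_compartments()] result.
#' @return named numeric vector: mean O/E for `A-A`, `B-B`, `A-B`.
#' @export
compartment_pair_strength <- function(m, profile) {
  g <- m$genome
  if (!same_genome(g, profile$genome)) stop("resolution/genome mismatch")
  if (all(is.na(profile$label))) stop("all bins unlabeled")
  sums <- c("A-A" = 0, "B-B" = 0, "A-B" = 0)
  ns <- c("A-A" = 0, "B-B" = 0, "A-B" = 0)
  for (k in seq_along(g$chrom)) {
    oe <- oe_chrom(m, g$chrom[k])
    idx <- (g$offset[k] + 1):(g$offset[k] + g$n_bins[k])
    lab <- profile$label[idx]
    n <- length(lab)
    pr <- which(upper.tri(oe), arr.ind = TRUE)
    li <- lab[pr[, 1]]; lj <- lab[pr[, 2]]
    v <- oe[pr]
    ok <- !is.na(li) & !is.na(lj) & !is.na(v)
    cls <- ifelse(li == lj, ifelse(li == "A", "A-A", "B-B"), "A-B")
    for (cl in names(sums)) {
      sel <- ok & cls == cl
      sums[cl] <- sums[cl] + sum(v[sel])
      ns[cl] <- ns[cl] + sum(sel)
    }
  }
  ifelse(ns > 0, sums / ns, NA_real_)
}

#' Pearson correlation of two contact matrices (replicate concordance)
#'
#' Computed on `log1p` counts over the union of nonzero bin pairs, with
#' zeros filled for pairs present in only one matrix.
#'
#' @param m1,m2 [contact_matrix()] objects on the same genome.
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(m1, m2) {
  if (!same_genome(m1$genome, m2$genome)) stop("resolution/genome mismatch")
  nb <- m1$genome$total_bins
  k1 <- m1$i * nb + m1$j
  k2 <- m2$i * nb + m2$j
  keys <- sort(unique(c(k1, k2)))
  if (!length(keys)) stop("no contact pairs in either matrix")
  x <- numeric(length(keys)); y <- numeric(length(keys))
  x[match(k1, keys)] <- m1$count
  y[match(k2, keys)] <- m2$count
  stats::cor(log1p(x), log1p(y))
}
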