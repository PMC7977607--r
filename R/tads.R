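# TAD calling by multi-window separation score on a distance z-scored
# contact matrix: local minima of the score are boundary candidates,
# filtered by a prominence (delta) threshold and an FDR on one-sided
# rank-sum tests of the boundary diamond against its flanks. Plus TAD
# set comparison across conditions: reciprocal-overlap sharing, size
# distributions and lost boundaries.

#' Distance-stratified z-score matrix
#'
#' For each chromosome and each bin separation `d <= max_distance`, raw
#' counts are standardized to zero mean and unit population sd within the
#' stratum (all pairs at that separation, zeros included); strata with
#' zero sd get z = 0. Entries beyond `max_distance` are NA.
#'
#' @param m a [contact_matrix()] at TAD resolution.
#' @param max_distance largest separation to standardize, in bp.
#' @return object of class `zscore_matrix`: per-chromosome dense matrix
#'   `z[[chrom]]` plus the stratum means/sds used.
#' @export
zscore_matrix <- function(m, max_distance) {
  g <- m$genome
  if (max_distance < g$bin_size) stop("max_distance smaller than bin size")
  dmax <- as.integer(floor(max_distance / g$bin_size))
  zs <- list(); stats_list <- list()
  for (k in seq_along(g$chrom)) {
    x <- dense_chrom(m, g$chrom[k])
    n <- nrow(x)
    z <- matrix(NA_real_, n, n)
    mu <- numeric(min(dmax, n - 1) + 1)
    sg <- numeric(length(mu))
    for (d in 0:min(dmax, n - 1)) {
      idx <- cbind(seq_len(n - d), seq_len(n - d) + d)
      v <- x[idx]
      m_d <- mean(v)
      s_d <- sqrt(mean((v - m_d)^2))  # population sd
      zv <- if (s_d > 0) (v - m_d) / s_d else rep(0, length(v))
      z[idx] <- zv
      z[idx[, c(2, 1), drop = FALSE]] <- zv
      mu[d + 1] <- m_d; sg[d + 1] <- s_d
    }
    zs[[g$chrom[k]]] <- z
    stats_list[[g$chrom[k]]] <- data.frame(d = 0:min(dmax, n - 1),
                                           mean = mu, sd = sg)
  }
  structure(list(genome = g, z = zs, stats = stats_list,
                 max_distance = max_distance),
            class = "zscore_matrix")
}

# diamond z-values at boundary p (1-based boundary between bin p and p+1)
# for window w bins: rows (p-w+1):p vs columns (p+1):(p+w)
diamond_values <- function(zmat, p, w) {
  as.vector(zmat[(p - w + 1):p, (p + 1):(p + w)])
}

#' Multi-window TAD-separation score
#'
#' For each inter-bin boundary and each window size `w`, the mean z-score
#' over the diamond of bin pairs linking the `w` bins upstream with the
#' `w` bins downstream; the final score is the unweighted mean over
#' window sizes. Boundaries where the largest window does not fit inside
#' the chromosome are masked.
#'
#' @param z a [zscore_matrix()].
#' @param window_sizes window sizes in bp (multiples of the bin size);
#'   default 15-30 kb in 5-kb steps scaled to the matrix resolution.
#' @return object of class `separation_track`: per-chromosome `score`
#'   (index p = boundary between bins p and p+1), `by_window` matrices,
#'   `window_bins`.
#' @export
separation_score <- function(z, window_sizes = NULL) {
  g <- z$genome
  if (is.null(window_sizes)) window_sizes <- g$bin_size * (3:6)
  if (any(window_sizes %% g$bin_size != 0))
    stop("window sizes must be multiples of the bin size")
  wb <- as.integer(window_sizes / g$bin_size)
  # the widest diamond reaches bin separation 2w - 1
  if ((2 * max(wb) - 1) * g$bin_size > z$max_distance)
    stop("z-score matrix band too narrow for the largest window")
  score <- list(); by_window <- list()
  for (chrom in g$chrom) {
    zm <- z$z[[chrom]]
    n <- nrow(zm)
    if (max(wb) * 2 > n) stop("window larger than chromosome ", chrom)
    comp <- matrix(NA_real_, n - 1, length(wb))
    for (wi in seq_along(wb)) {
      w <- wb[wi]
      for (p in w:(n - w)) comp[p, wi] <- mean(diamond_values(zm, p, w))
    }
    wmax <- max(wb)
    s <- rowMeans(comp)
    s[seq_len(n - 1) < wmax | seq_len(n - 1) > n - wmax] <- NA_real_
    score[[chrom]] <- s
    by_window[[chrom]] <- comp
  }
  structure(list(genome = g, score = score, by_window = by_window,
                 window_bins = wb, window_sizes = window_sizes),
            class = "separation_track")
}

# strict local minima / flanking maxima over the defined part of a track
local_extrema <- function(s) {
  def <- which(!is.na(s))
  mins <- integer(0)
  for (p in def) {
    if ((p - 1) %in% def && (p + 1) %in% def &&
        s[p] < s[p - 1] && s[p] < s[p + 1]) mins <- c(mins, p)
  }
  mins
}

#' Call TAD boundaries from a separation track
#'
#' Candidates are strict local minima of the score. For each candidate,
#' `delta` is the mean score of the two flanking local maxima minus the
#' candidate score, and the p-value is the larger of two one-sided
#' Mann-Whitney p-values comparing the candidate's diamond z-values
#' against each flanking maximum's diamond (alternative: candidate lower).
#' P-values are BH-adjusted over all candidates genome-wide; a boundary
#' is accepted when `q <= q_threshold` and `delta >= delta_threshold`.
#'
#' @param track a [separation_score()] result.
#' @param z the [zscore_matrix()] the track was computed from.
#' @param delta_threshold minimum prominence (default 0.01).
#' @param q_threshold BH-adjusted p cutoff (default 0.05).
#' @return data.frame of class `boundary_calls`: `chrom`, `pos` (bp),
#'   `boundary_index`, `score`, `delta`, `pvalue`, `qvalue`, `accepted`.
#' @export
call_boundaries <- function(track, z, delta_threshold = 0.01,
                            q_threshold = 0.05) {
  g <- track$genome
  wmax <- max(track$window_bins)
  out <- list()
  for (chrom in g$chrom) {
    s <- track$score[[chrom]]
    if (sum(!is.na(s)) < 3) stop("track too short on ", chrom)
    zm <- z$z[[chrom]]
    mins <- local_extrema(s)
    if (!length(mins)) next
    def <- which(!is.na(s))
    for (p in mins) {
      # flanking maxima: highest score between this minimum and the
      # adjacent candidate minimum (or the end of the defined track)
      left_lim <- max(c(def[1], mins[mins < p] + 1L))
      right_lim <- min(c(def[length(def)], mins[mins > p] - 1L))
      lmax <- (left_lim:(p - 1))[which.max(s[left_lim:(p - 1)])]
      rmax <- ((p + 1):right_lim)[which.max(s[(p + 1):right_lim])]
      delta <- mean(c(s[lmax], s[rmax])) - s[p]
      dp <- diamond_values(zm, p, wmax)
      pl <- suppressWarnings(stats::wilcox.test(
        dp, diamond_values(zm, lmax, wmax), alternative = "less"))$p.value
      pr <- suppressWarnings(stats::wilcox.test(
        dp, diamond_values(zm, rmax, wmax), alternative = "less"))$p.value
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, pos = p * g$bin_size, boundary_index = p,
        score = s[p], delta = delta, pvalue = max(pl, pr),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    res <- data.frame(chrom = character(), pos = numeric(),
                      boundary_index = integer(), score = numeric(),
                      delta = numeric(), pvalue = numeric(),
                      qvalue = numeric(), accepted = logical())
  } else {
    res <- do.call(rbind, out)
    res$qvalue <- stats::p.adjust(res$pvalue, method = "BH")
    res$accepted <- res$qvalue <= q_threshold & res$delta >= delta_threshold
  }
  class(res) <- c("boundary_calls", "data.frame")
  attr(res, "genome") <- g
  res
}

#' Build TAD domains from accepted boundaries
#'
#' Consecutive accepted boundaries delimit domains; chromosome ends are
#' implicit boundaries. Domains shorter than `min_size` are merged into a
#' neighbor by dissolving the weaker (higher-score) of their two
#' delimiting boundaries.
#'
#' @param calls a [call_boundaries()] result (or any data.frame with
#'   `chrom`, `pos`, `score`, `accepted`).
#' @param genome a [genome_spec()].
#' @param min_size minimum domain size in bp (default 3 bins).
#' @return object of class `tad_set`: `domains` data.frame (`chrom`,
#'   `start`, `end`, `size`), `boundaries` (interior, bp), `genome`.
#' @export
domains_from_boundaries <- function(calls, genome, min_size = NULL) {
  if (is.null(min_size)) min_size <- 3 * genome$bin_size
  doms <- list(); bds <- list()
  for (k in seq_along(genome$chrom)) {
    chrom <- genome$chrom[k]
    acc <- calls[calls$chrom == chrom & calls$accepted, , drop = FALSE]
    pos <- acc$pos[order(acc$pos)]
    sc <- if ("score" %in% names(acc)) acc$score[order(acc$pos)] else
      rep(0, length(pos))
    repeat {
      edges <- c(0, pos, genome$length[k])
      sizes <- diff(edges)
      small <- which(sizes < min_size)
      if (!length(small) || !length(pos)) break
      dix <- small[which.min(sizes[small])]
      # delimiting boundaries of domain dix: pos index dix-1 (left) and
      # dix (right); dissolve the one with the higher separation score
      lb <- dix - 1L; rb <- dix
      drop_idx <- if (lb < 1) rb
        else if (rb > length(pos)) lb
        else if (sc[lb] > sc[rb]) lb else rb
      pos <- pos[-drop_idx]; sc <- sc[-drop_idx]
    }
    edges <- c(0, pos, genome$length[k])
    doms[[k]] <- data.frame(chrom = chrom, start = edges[-length(edges)],
                            end = edges[-1], stringsAsFactors = FALSE)
    bds[[k]] <- data.frame(chrom = rep(chrom, length(pos)), pos = pos,
                           stringsAsFactors = FALSE)
  }
  domains <- do.call(rbind, doms)
  domains$size <- domains$end - domains$start
  structure(list(genome = genome, domains = domains,
                 boundaries = do.call(rbind, bds)),
            class = "tad_set")
}

#' @export
print.tad_set <- function(x, ...) {
  cat(sprintf("tad_set: %d domains, median size %g bp\n",
              nrow(x$domains), stats::median(x$domains$size)))
  invisible(x)
}

#' Shared and set-specific TADs by reciprocal overlap
#'
#' A pair is shared when the overlap covers at least `fraction` of both
#' domains; each domain joins at most one pair, assigned greedily by
#' descending overlap.
#'
#' @param set1,set2 [domains_from_boundaries()] results on one genome.
#' @param fraction reciprocal overlap fraction (default 0.8).
#' @return list: `pairs` (indices + overlap bp), `n_shared`, `n_set1_only`,
#'   `n_set2_only`.
#' @export
shared_tads <- function(set1, set2, fraction = 0.8) {
  if (!same_genome(set1$genome, set2$genome)) stop("different genomes")
  stopifnot(fraction > 0, fraction <= 1)
  d1 <- set1$domains; d2 <- set2$domains
  gr1 <- GenomicRanges::GRanges(d1$chrom,
          IRanges::IRanges(d1$start + 1, d1$end))
  gr2 <- GenomicRanges::GRanges(d2$chrom,
          IRanges::IRanges(d2$start + 1, d2$end))
  hits <- GenomicRanges::findOverlaps(gr1, gr2)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr1)[q],
                                           IRanges::ranges(gr2)[s]))
  ok <- ov >= fraction * d1$size[q] & ov >= fraction * d2$size[s]
  q <- q[ok]; s <- s[ok]; ov <- ov[ok]
  ord <- order(-ov)
  used1 <- logical(nrow(d1)); used2 <- logical(nrow(d2))
  pairs <- list()
  for (h in ord) {
    if (!used1[q[h]] && !used2[s[h]]) {
      used1[q[h]] <- TRUE; used2[s[h]] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(q[h], s[h], ov[h])
    }
  }
  pairs <- if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    data.frame(set1_idx = pm[, 1], set2_idx = pm[, 2], overlap = pm[, 3])
  } else data.frame(set1_idx = integer(), set2_idx = integer(),
                    overlap = numeric())
  list(pairs = pairs, n_shared = nrow(pairs),
       n_set1_only = nrow(d1) - nrow(pairs),
       n_set2_only = nrow(d2) - nrow(pairs))
}

# majority compartment label of a domain at the profile's resolution
domain_compartment <- function(tads, profile) {
  d <- tads$domains
  vapply(seq_len(nrow(d)), function(r) {
    g <- profile$genome
    b0 <- bin_of(d$chrom[r], d$start[r], g)
    b1 <- bin_of(d$chrom[r], min(d$end[r] - 1,
                                 g$length[match(d$chrom[r], g$chrom)] - 1), g)
    labs <- profile$label[(b0 + 1):(b1 + 1)]
    nA <- sum(labs == "A", na.rm = TRUE); nB <- sum(labs == "B", na.rm = TRUE)
    if (nA == 0 && nB == 0) NA_character_ else if (nA >= nB) "A" else "B"
  }, character(1))
}

#' Compare TAD size distributions between two sets
#'
#' Two-sided Mann-Whitney test on domain sizes, optionally stratified by
#' the majority compartment label of each domain.
#'
#' @param set1,set2 [domains_from_boundaries()] results.
#' @param compartments optional [call_compartments()] profile for
#'   stratification.
#' @return data.frame: one row per stratum ("all" plus labels) with
#'   `n1`, `n2`, `median1`, `median2`, `pvalue` (NA when a stratum is
#'   empty on either side, with `flagged = TRUE`).
#' @export
compare_tad_sizes <- function(set1, set2, compartments = NULL) {
  if (!nrow(set1$domains) || !nrow(set2$domains)) stop("empty TAD set")
  strata <- list(all = list(set1$domains$size, set2$domains$size))
  if (!is.null(compartments)) {
    l1 <- domain_compartment(set1, compartments)
    l2 <- domain_compartment(set2, compartments)
    for (lab in c("A", "B")) {
      strata[[lab]] <- list(set1$domains$size[l1 == lab & !is.na(l1)],
                            set2$domains$size[l2 == lab & !is.na(l2)])
    }
  }
  do.call(rbind, lapply(names(strata), function(nm) {
    a <- strata[[nm]][[1]]; b <- strata[[nm]][[2]]
    empty <- !length(a) || !length(b)
    p <- if (empty) NA_real_ else
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    data.frame(stratum = nm, n1 = length(a), n2 = length(b),
               median1 = if (length(a)) stats::median(a) else NA_real_,
               median2 = if (length(b)) stats::median(b) else NA_real_,
               pvalue = p, flagged = empty, stringsAsFactors = FALSE)
  }))
}

#' Boundaries lost between conditions, annotated by local switch class
#'
#' A condition-1 boundary is lost when no condition-2 boundary lies
#' within `tol` bins of it. Each lost boundary is annotated with the
#' compartment-switch class of the bin containing it.
#'
#' @param set1,set2 [domains_from_boundaries()] results
#'   (condition 1, condition 2).
#' @param switch optional [classify_switches()] result for annotation.
#' @param tol matching tolerance in bins of `set1`'s genome (default 1).
#' @return list: `lost` (data.frame with `chrom`, `pos`, `switch_class`),
#'   `n_lost`, `n_boundaries1`, `class_tally`.
#' @export
lost_boundaries <- function(set1, set2, switch = NULL, tol = 1) {
  b1 <- set1$boundaries; b2 <- set2$boundaries
  tol_bp <- tol * set1$genome$bin_size
  lost <- logical(nrow(b1))
  for (r in seq_len(nrow(b1))) {
    near <- b2$pos[b2$chrom == b1$chrom[r]]
    lost[r] <- !length(near) || min(abs(near - b1$pos[r])) > tol_bp
  }
  lost_df <- b1[lost, , drop = FALSE]
  if (!is.null(switch) && nrow(lost_df)) {
    lost_df$switch_class <- switch_class_at(
      switch, lost_df$chrom, pmin(lost_df$pos,
        switch$genome$length[match(lost_df$chrom, switch$genome$chrom)] - 1))
  } else if (nrow(lost_df)) {
    lost_df$switch_class <- NA_character_
  } else {
    lost_df$switch_class <- character(0)
  }
  rownames(lost_df) <- NULL
  list(lost = lost_df, n_lost = sum(lost), n_boundaries1 = nrow(b1),
       class_tally = table(factor(lost_df$switch_class,
                                  levels = c("A-A", "B-B", "A-B", "B-A"))))
}
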