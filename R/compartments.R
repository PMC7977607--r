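# A/B compartment calling: distance-expected normalization (O/E),
# per-chromosome Pearson correlation matrix, PCA by eigendecomposition,
# gene-density sign orientation, and per-bin switch classification
# between two conditions.

#' Mean contact count per genomic distance (expected model)
#'
#' The distance-decay background used for observed/expected (O/E)
#' normalization: for each bin separation `d` the mean raw count over
#' all intra-chromosomal bin pairs at that separation, zeros included.
#'
#' @param m a [contact_matrix()].
#' @param chrom chromosome name.
#' @return numeric vector of length `n_bins(chrom)`, index `d + 1` holding
#'   the mean at separation `d` bins.
#' @export
expected_by_distance <- function(m, chrom) {
  g <- m$genome
  ci <- match(chrom, g$chrom)
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  n <- g$n_bins[ci]; off <- g$offset[ci]
  sel <- m$i >= off & m$i < off + n & m$j >= off & m$j < off + n
  d <- m$j[sel] - m$i[sel]
  sums <- numeric(n)
  if (any(sel)) {
    agg <- rowsum(m$count[sel], group = d)
    sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  n_pairs <- n - (seq_len(n) - 1L)
  sums / n_pairs
}

# dense O/E matrix for one chromosome; entries with expected == 0 are NA
oe_chrom <- function(m, chrom) {
  x <- dense_chrom(m, chrom)
  exp_d <- expected_by_distance(m, chrom)
  n <- nrow(x)
  d <- abs(row(x) - col(x))
  e <- matrix(exp_d[d + 1L], n, n)
  oe <- x / e
  oe[e == 0] <- NA
  oe
}

# low-coverage bin mask: zero raw marginal, or > 50% of O/E row undefined
compartment_mask <- function(m, chrom) {
  x <- dense_chrom(m, chrom)
  oe <- oe_chrom(m, chrom)
  marg <- rowSums(x)
  frac_na <- rowMeans(is.na(oe))
  marg == 0 | frac_na > 0.5
}

#' Per-chromosome Pearson correlation matrix of O/E contact profiles
#'
#' Entry (i,j) is the Pearson correlation of the O/E rows of bins i and j
#' over unmasked columns (pairwise-complete where O/E is undefined).
#' Masked bins get NA rows/columns; the diagonal is 1 on unmasked bins.
#'
#' @param m a [contact_matrix()].
#' @param chrom chromosome name.
#' @param mask optional logical vector (TRUE = exclude); defaults to the
#'   zero-marginal / low-coverage mask.
#' @return dense symmetric correlation matrix.
#' @export
correlation_matrix <- function(m, chrom, mask = NULL) {
  oe <- oe_chrom(m, chrom)
  n <- nrow(oe)
  if (is.null(mask)) mask <- compartment_mask(m, chrom)
  keep <- which(!mask)
  if (length(keep) < 3) stop("fewer than 3 unmasked bins on ", chrom)
  sub <- oe[keep, keep, drop = FALSE]
  cm_sub <- suppressWarnings(
    stats::cor(sub, use = "pairwise.complete.obs"))
  diag(cm_sub) <- 1
  cm <- matrix(NA_real_, n, n)
  cm[keep, keep] <- cm_sub
  cm
}

#' Call A/B compartments from a contact matrix
#'
#' Per chromosome: PC1 is the leading eigenvector of the O/E Pearson
#' correlation matrix, scaled by the square root of its eigenvalue, and
#' sign-oriented so it correlates non-negatively with per-bin gene
#' density (the A compartment is gene-rich). Bins with positive PC1 are
#' labeled A, negative B, masked bins NA.
#'
#' @param m a [contact_matrix()] at compartment resolution.
#' @param genes gene interval table (used for per-bin gene density).
#' @return object of class `compartment_profile`: `genome`, `pc1`
#'   (per-bin, NA where masked), `label` ("A"/"B"/NA), `oriented_flip`
#'   (per chromosome), `resolution`.
#' @export
call_compartments <- function(m, genes) {
  g <- m$genome
  if (nrow(genes) == 0) stop("gene set is empty")
  gd <- gene_density(genes, g)
  pc1 <- rep(NA_real_, g$total_bins)
  flip <- stats::setNames(logical(length(g$chrom)), g$chrom)
  for (k in seq_along(g$chrom)) {
    chrom <- g$chrom[k]
    mask <- compartment_mask(m, chrom)
    cm <- correlation_matrix(m, chrom, mask)
    keep <- which(!mask)
    sub <- cm[keep, keep, drop = FALSE]
    sub[is.na(sub)] <- 0
    eig <- eigen(sub, symmetric = TRUE)
    if (eig$values[1] <= 0) stop("degenerate correlation matrix on ", chrom)
    v <- eig$vectors[, 1] * sqrt(eig$values[1])
    dens <- gd[g$offset[k] + keep]
    rho <- suppressWarnings(stats::cor(v, dens))
    if (!is.na(rho) && rho < 0) { v <- -v; flip[k] <- TRUE }
    pc1[g$offset[k] + keep] <- v
  }
  label <- ifelse(is.na(pc1), NA_character_,
                  ifelse(pc1 > 0, "A", ifelse(pc1 < 0, "B", NA_character_)))
  structure(list(genome = g, pc1 = pc1, label = label,
                 oriented_flip = flip, resolution = g$bin_size),
            class = "compartment_profile")
}

#' Per-bin gene density (midpoint counts)
#' @param genes gene interval table.
#' @param genome a [genome_spec()].
#' @return integer vector, genes per bin.
#' @export
gene_density <- function(genes, genome) {
  b <- bin_of(genes$chrom, midpoints(genes), genome)
  tabulate(b + 1L, nbins = genome$total_bins)
}

#' Classify per-bin compartment switching between two conditions
#'
#' Classes are A-A / B-B (stable) and A-B / B-A (switching, condition-1
#' label first). A bin is NA when either profile is masked or its |PC1|
#' falls below a per-chromosome dead zone of
#' `epsilon_factor * sd(PC1 on that chromosome)`, which suppresses
#' sign-noise switches near zero. Contiguous bins of one switching class
#' are merged into segments.
#'
#' @param p1,p2 [call_compartments()] profiles for condition 1 and 2.
#' @param epsilon_factor dead-zone width as a fraction of the
#'   per-chromosome PC1 sd (default 0.01).
#' @return object of class `switch_call`: per-bin `class`, `segments`
#'   (intervals of the two switching classes), `bin_counts`,
#'   `segment_counts`.
#' @export
classify_switches <- function(p1, p2, epsilon_factor = 0.01) {
  if (!same_genome(p1$genome, p2$genome) || p1$resolution != p2$resolution)
    stop("profiles have different genomes or resolutions")
  g <- p1$genome
  eps_of <- function(p) {
    eps <- numeric(g$total_bins)
    for (k in seq_along(g$chrom)) {
      idx <- (g$offset[k] + 1):(g$offset[k] + g$n_bins[k])
      s <- stats::sd(p$pc1[idx], na.rm = TRUE)
      eps[idx] <- if (is.na(s)) 0 else epsilon_factor * s
    }
    eps
  }
  ok1 <- !is.na(p1$pc1) & abs(p1$pc1) >= eps_of(p1)
  ok2 <- !is.na(p2$pc1) & abs(p2$pc1) >= eps_of(p2)
  cls <- rep(NA_character_, g$total_bins)
  both <- ok1 & ok2
  cls[both] <- paste0(p1$label[both], "-", p2$label[both])
  bin_counts <- table(factor(cls, levels = c("A-A", "B-B", "A-B", "B-A")))
  # maximal runs of one switching class -> segments
  segs <- list()
  for (k in seq_along(g$chrom)) {
    idx <- (g$offset[k] + 1):(g$offset[k] + g$n_bins[k])
    ck <- cls[idx]
    sw <- ck %in% c("A-B", "B-A")
    if (!any(sw)) next
    r <- rle(ifelse(sw, ck, "other"))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (s in which(r$values %in% c("A-B", "B-A"))) {
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = g$chrom[k],
        start = (starts[s] - 1) * g$bin_size,
        end = min(ends[s] * g$bin_size, g$length[k]),
        class = r$values[s], stringsAsFactors = FALSE)
    }
  }
  segs <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               class = character(), stringsAsFactors = FALSE)
  structure(list(genome = g, class = cls, segments = segs,
                 bin_counts = bin_counts,
                 segment_counts = table(factor(segs$class,
                                               levels = c("A-B", "B-A")))),
            class = "switch_call")
}

#' Per-bin switch class at arbitrary positions
#' @param sw a [classify_switches()] result.
#' @param chrom,pos positions (0-based bp).
#' @return character vector of classes (NA outside calls).
#' @export
switch_class_at <- function(sw, chrom, pos) {
  sw$class[bin_of(chrom, pos, sw$genome) + 1L]
}
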