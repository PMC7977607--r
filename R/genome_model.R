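# Core data types and on-disk formats: genome binning, sparse contact
# matrices (HiC-Pro "abs bed + triplet" dialect), BED intervals, per-bin
# signal tracks and replicated count tables.
#
# Conventions: 0-based half-open coordinates everywhere in memory; bin ids
# are 1-based on disk (HiC-Pro) and 0-based global indices in memory.

#' Genome specification with a fixed bin size
#'
#' Defines the coordinate system every other object in the package works
#' in: an ordered set of chromosomes and a fixed bin width. Bins are
#' 0-based half-open; the last bin of a chromosome may be shorter.
#'
#' @param lengths named numeric vector of chromosome lengths in bp
#'   (names are chromosome names, order is kept).
#' @param bin_size bin width in bp.
#' @return an object of class `genome_spec` with elements `chrom`,
#'   `length`, `bin_size`, `n_bins` (per chromosome), `offset`
#'   (global index of each chromosome's first bin) and `total_bins`.
#' @export
genome_spec <- function(lengths, bin_size) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicate chromosome names")
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  if (length(bin_size) != 1L || bin_size <= 0) stop("bin_size must be > 0")
  n_bins <- as.integer(ceiling(lengths / bin_size))
  g <- list(
    chrom = names(lengths),
    length = as.numeric(unname(lengths)),
    bin_size = as.numeric(bin_size),
    n_bins = n_bins,
    offset = c(0L, cumsum(n_bins)[-length(n_bins)]),
    total_bins = sum(n_bins)
  )
  names(g$length) <- g$chrom
  names(g$n_bins) <- g$chrom
  names(g$offset) <- g$chrom
  class(g) <- "genome_spec"
  g
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosome(s), bin_size %g bp, %d bins\n",
              length(x$chrom), x$bin_size, x$total_bins))
  invisible(x)
}

same_genome <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(a$length, b$length) &&
    identical(a$bin_size, b$bin_size)
}

#' Map a genomic position to its global bin index
#'
#' @param chrom chromosome name(s).
#' @param pos 0-based position(s) in bp; must be `< length(chrom)`.
#' @param genome a [genome_spec()].
#' @return 0-based global bin index (integer vector).
#' @export
bin_of <- function(chrom, pos, genome) {
  ci <- match(chrom, genome$chrom)
  if (anyNA(ci)) stop("unknown chromosome: ", chrom[which(is.na(ci))[1]])
  if (any(pos < 0) || any(pos >= genome$length[ci]))
    stop("position outside chromosome bounds")
  as.integer(genome$offset[ci] + floor(pos / genome$bin_size))
}

#' Chromosome and local bin index of global bin indices
#' @param bin 0-based global bin indices.
#' @param genome a [genome_spec()].
#' @return data.frame with `chrom`, `bin_local` (0-based within
#'   chromosome), `start`, `end` (bp, half-open).
#' @export
bin_table <- function(bin, genome) {
  if (any(bin < 0) || any(bin >= genome$total_bins))
    stop("bin index out of range")
  ci <- findInterval(bin, genome$offset)
  loc <- bin - genome$offset[ci]
  start <- loc * genome$bin_size
  data.frame(
    chrom = genome$chrom[ci],
    bin_local = as.integer(loc),
    start = start,
    end = pmin(start + genome$bin_size, genome$length[ci]),
    stringsAsFactors = FALSE
  )
}

#' Sparse symmetric contact matrix
#'
#' Stores binned Hi-C contacts in upper-triangle triplet form
#' (`bin_i <= bin_j`, 0-based global indices). Duplicate entries are
#' summed; symmetry is implicit.
#'
#' @param genome a [genome_spec()].
#' @param i,j 0-based global bin indices.
#' @param count non-negative contact counts (real-valued: normalized
#'   matrices are allowed).
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(genome, i, j, count) {
  stopifnot(inherits(genome, "genome_spec"))
  if (length(i) != length(j) || length(i) != length(count))
    stop("i, j, count must have equal length")
  if (length(i)) {
    if (any(i < 0) || any(j < 0) || any(i >= genome$total_bins) ||
        any(j >= genome$total_bins))
      stop("bin index out of range")
    if (any(count < 0)) stop("negative count")
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- lo * genome$total_bins + hi
  if (anyDuplicated(key)) {
    agg <- rowsum(as.numeric(count), group = key, reorder = TRUE)
    key <- as.numeric(rownames(agg))
    count <- as.numeric(agg[, 1])
    lo <- as.integer(key %/% genome$total_bins)
    hi <- as.integer(key %% genome$total_bins)
  } else {
    ord <- order(key)
    lo <- lo[ord]; hi <- hi[ord]; count <- as.numeric(count)[ord]
  }
  keep <- count != 0
  m <- list(genome = genome, i = lo[keep], j = hi[keep],
            count = count[keep], resolution = genome$bin_size)
  class(m) <- "contact_matrix"
  m
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins (%g bp), %d nonzero pairs, total %g\n",
              x$genome$total_bins, x$resolution, length(x$i), sum(x$count)))
  invisible(x)
}

#' Dense symmetric intra-chromosomal submatrix
#'
#' @param m a [contact_matrix()].
#' @param chrom chromosome name.
#' @return dense numeric matrix (n_bins x n_bins) with zeros filled in.
#' @export
dense_chrom <- function(m, chrom) {
  g <- m$genome
  ci <- match(chrom, g$chrom)
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  off <- g$offset[ci]; n <- g$n_bins[ci]
  sel <- m$i >= off & m$i < off + n & m$j >= off & m$j < off + n
  x <- matrix(0, n, n)
  if (any(sel)) {
    ii <- m$i[sel] - off + 1L; jj <- m$j[sel] - off + 1L
    x[cbind(ii, jj)] <- m$count[sel]
    x[cbind(jj, ii)] <- m$count[sel]
  }
  x
}

#' Aggregate a contact matrix to a coarser resolution by summation
#'
#' @param m a [contact_matrix()].
#' @param new_bin_size target bin size, a multiple of the current one.
#' @return a [contact_matrix()] at the new resolution.
#' @export
aggregate_matrix <- function(m, new_bin_size) {
  g <- m$genome
  if (new_bin_size %% g$bin_size != 0)
    stop("new_bin_size must be a multiple of the current bin size")
  g2 <- genome_spec(stats::setNames(g$length, g$chrom), new_bin_size)
  bt_i <- bin_table(m$i, g)
  bt_j <- bin_table(m$j, g)
  i2 <- bin_of(bt_i$chrom, bt_i$start, g2)
  j2 <- bin_of(bt_j$chrom, bt_j$start, g2)
  contact_matrix(g2, i2, j2, m$count)
}

format_header <- function() {
  sprintf("# chromoshift %s", as.character(utils::packageVersion("chromoshift")))
}

#' Read a HiC-Pro style sparse matrix (bins BED + triplet file)
#'
#' The bins file is BED-like (`chrom start end bin_id`) with 1-based
#' sequential bin ids; the matrix file holds whitespace-separated
#' `bin_i bin_j count` triplets (1-based ids). Lower-triangle entries are
#' mirrored and duplicate pairs are summed.
#'
#' @param bins_path path to the bins BED file.
#' @param matrix_path path to the triplet file.
#' @return a [contact_matrix()]; the genome spec is inferred from the bins.
#' @export
read_matrix <- function(bins_path, matrix_path) {
  bins <- utils::read.table(bins_path, header = FALSE, sep = "",
                            comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(bins) < 4) stop("bins file needs 4 columns: chrom start end id")
  names(bins)[1:4] <- c("chrom", "start", "end", "id")
  if (any(bins$start >= bins$end)) {
    bad <- which(bins$start >= bins$end)[1]
    stop("bins file line ", bad, ": start >= end")
  }
  widths <- bins$end - bins$start
  bin_size <- max(widths)
  lengths <- tapply(bins$end, bins$chrom, max)
  # keep chromosome order of first appearance, not alphabetical
  ord <- unique(bins$chrom)
  lengths <- stats::setNames(as.numeric(lengths[ord]), ord)
  genome <- genome_spec(lengths, bin_size)
  expected_id <- bin_of(bins$chrom, bins$start, genome) + 1L
  if (!all(bins$id == expected_id))
    stop("bins file line ", which(bins$id != expected_id)[1],
         ": bin ids are not sequential in genome order")
  trip <- tryCatch(
    utils::read.table(matrix_path, header = FALSE, sep = "",
                      comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        data.frame() else stop(e)
    })
  if (nrow(trip) == 0)
    return(contact_matrix(genome, integer(), integer(), numeric()))
  if (ncol(trip) != 3) stop("matrix file must have 3 columns")
  if (any(trip[[1]] < 1 | trip[[1]] > genome$total_bins |
          trip[[2]] < 1 | trip[[2]] > genome$total_bins)) {
    bad <- which(trip[[1]] < 1 | trip[[1]] > genome$total_bins |
                 trip[[2]] < 1 | trip[[2]] > genome$total_bins)[1]
    stop("matrix file line ", bad, ": bin index out of range")
  }
  if (any(trip[[3]] < 0)) {
    stop("matrix file line ", which(trip[[3]] < 0)[1], ": negative count")
  }
  contact_matrix(genome, as.integer(trip[[1]]) - 1L,
                 as.integer(trip[[2]]) - 1L, trip[[3]])
}

#' Write a contact matrix as bins BED + triplet file
#'
#' @param m a [contact_matrix()].
#' @param out_prefix output path prefix; writes `<prefix>_abs.bed` and
#'   `<prefix>.matrix`.
#' @return invisibly, the two paths written.
#' @export
write_matrix <- function(m, out_prefix) {
  g <- m$genome
  bins_path <- paste0(out_prefix, "_abs.bed")
  mat_path <- paste0(out_prefix, ".matrix")
  bt <- bin_table(seq_len(g$total_bins) - 1L, g)
  con <- file(bins_path, "w")
  writeLines(format_header(), con)
  utils::write.table(
    data.frame(bt$chrom, format_bp(bt$start), format_bp(bt$end),
               seq_len(g$total_bins)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  con <- file(mat_path, "w")
  writeLines(format_header(), con)
  if (length(m$i))
    utils::write.table(
      data.frame(m$i + 1L, m$j + 1L, format_num(m$count)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(c(bins = bins_path, matrix = mat_path))
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
format_num <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
         format(x, digits = 15, trim = TRUE))
}

#' Read genomic intervals from BED3/BED6
#'
#' @param path BED file; either all lines BED3 or all BED6
#'   (`chrom start end name score strand`).
#' @param kind feature kind tag attached to every interval
#'   (gene, TE, peak, site, TAD, block).
#' @param genome optional [genome_spec()] to validate against.
#' @return data.frame with columns `chrom`, `start`, `end`, `id`,
#'   `strand`, `kind`; input order preserved.
#' @export
read_intervals <- function(path, kind = "peak", genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(intervals(character(), numeric(), numeric(), kind = kind))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (!all(nf == nf[1]))
    stop("mixed BED dialects: line ", which(nf != nf[1])[1],
         " has ", nf[which(nf != nf[1])[1]], " fields, expected ", nf[1])
  if (!nf[1] %in% c(3L, 6L)) stop("expected BED3 or BED6, got ", nf[1], " fields")
  mat <- do.call(rbind, fields)
  start <- as.numeric(mat[, 2]); end <- as.numeric(mat[, 3])
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad)) stop("line ", bad[1], ": start >= end (empty interval)")
  if (nf[1] == 6L) {
    strand <- mat[, 6]
    if (!all(strand %in% c("+", "-", ".")))
      stop("line ", which(!strand %in% c("+", "-", "."))[1],
           ": unknown strand symbol")
    iv <- intervals(mat[, 1], start, end, id = mat[, 4],
                    strand = strand, kind = kind)
  } else {
    iv <- intervals(mat[, 1], start, end, kind = kind)
  }
  if (!is.null(genome)) validate_intervals(iv, genome)
  iv
}

#' Construct a validated interval table
#'
#' @param chrom,start,end vectors defining 0-based half-open intervals.
#' @param id feature identifiers (auto-generated when missing).
#' @param strand `+`, `-` or `.`.
#' @param kind feature kind tag.
#' @return data.frame of class `c("intervals", "data.frame")`.
#' @export
intervals <- function(chrom, start, end, id = NULL, strand = ".",
                      kind = "peak") {
  n <- length(chrom)
  if (is.null(id)) id <- if (n) sprintf("%s_%05d", kind, seq_len(n)) else character()
  if (length(strand) == 1L) strand <- rep(strand, n)
  if (n && any(start >= end)) stop("start >= end")
  if (n && !all(strand %in% c("+", "-", "."))) stop("unknown strand symbol")
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), id = as.character(id),
                    strand = as.character(strand), kind = kind,
                    stringsAsFactors = FALSE)
  class(out) <- c("intervals", "data.frame")
  out
}

validate_intervals <- function(iv, genome) {
  ci <- match(iv$chrom, genome$chrom)
  if (anyNA(ci)) stop("unknown chromosome: ", iv$chrom[which(is.na(ci))[1]])
  if (any(iv$end > genome$length[ci])) stop("interval beyond chromosome end")
  invisible(iv)
}

#' Write intervals as BED6
#' @param iv an [intervals()] table.
#' @param path output path.
#' @export
write_intervals <- function(iv, path) {
  con <- file(path, "w")
  writeLines(format_header(), con)
  if (nrow(iv))
    utils::write.table(
      data.frame(iv$chrom, format_bp(iv$start), format_bp(iv$end),
                 iv$id, 0L, iv$strand),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

iv_to_granges <- function(iv) {
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1, end = iv$end),
    strand = ifelse(iv$strand == ".", "*", iv$strand))
}

#' Feature midpoints (bp, 0-based)
#' @param iv an [intervals()] table.
#' @export
midpoints <- function(iv) floor((iv$start + iv$end) / 2)

#' Per-bin signal track
#'
#' @param genome a [genome_spec()].
#' @param values numeric vector of length `genome$total_bins`; `NA` marks
#'   masked bins.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(genome, values) {
  if (length(values) != genome$total_bins)
    stop("values must have one entry per bin")
  if (any(is.infinite(values))) stop("values must be finite or NA")
  structure(list(genome = genome, values = as.numeric(values)),
            class = "signal_track")
}

#' Write a per-bin track as bedGraph
#' @param track a [signal_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  g <- track$genome
  bt <- bin_table(seq_len(g$total_bins) - 1L, g)
  keep <- !is.na(track$values)
  con <- file(path, "w")
  writeLines(format_header(), con)
  if (any(keep))
    utils::write.table(
      data.frame(bt$chrom[keep], format_bp(bt$start[keep]),
                 format_bp(bt$end[keep]),
                 format(track$values[keep], digits = 8, trim = TRUE)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Replicated count table with a sample-to-condition map
#'
#' @param counts integer matrix, features x samples, with rownames
#'   (feature ids) and colnames (sample ids).
#' @param condition character vector, one condition label per column.
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts need unique feature ids as rownames")
  if (length(condition) != ncol(counts))
    stop("one condition label per sample column required")
  if (any(counts < 0)) stop("negative counts")
  structure(list(counts = counts, condition = as.character(condition)),
            class = "count_table")
}

#' Write a count table as TSV (condition map in a header comment)
#' @param ct a [count_table()].
#' @param path output path.
#' @export
write_counts <- function(ct, path) {
  con <- file(path, "w")
  writeLines(format_header(), con)
  writeLines(paste0("#condition\t", paste(ct$condition, collapse = "\t")), con)
  writeLines(paste(c("feature_id", colnames(ct$counts)), collapse = "\t"), con)
  utils::write.table(
    data.frame(rownames(ct$counts), ct$counts, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a count table written by [write_counts()]
#' @param path TSV path.
#' @export
read_counts <- function(path) {
  lines <- readLines(path, n = 10L)
  cond_line <- grep("^#condition\t", lines, value = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  condition <- if (length(cond_line)) {
    strsplit(sub("^#condition\t", "", cond_line[1]), "\t")[[1]]
  } else sub("[._][^._]*$", "", colnames(counts))
  count_table(counts, condition)
}
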