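# Shared fixtures, built once per test run. The default bundle is the
# generator at its default (study) conditions with seed 1; TAD calls on
# it are cached because several files need them.

.fixtures <- new.env()

default_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- simulate_bundle(sim_config(seed = 1))
  .fixtures$bundle
}

default_profiles <- function() {
  if (is.null(.fixtures$profiles)) {
    b <- default_bundle()
    .fixtures$profiles <- list(
      p1 = call_compartments(b$hic_comp[[1]], b$genes),
      p2 = call_compartments(b$hic_comp[[2]], b$genes))
  }
  .fixtures$profiles
}

default_switches <- function() {
  if (is.null(.fixtures$switches)) {
    pr <- default_profiles()
    .fixtures$switches <- classify_switches(pr$p1, pr$p2)
  }
  .fixtures$switches
}

default_tads <- function(condition) {
  key <- paste0("tads", condition)
  if (is.null(.fixtures[[key]])) {
    b <- default_bundle()
    m <- b$hic[[condition]]
    ws <- m$genome$bin_size * (3:6)
    z <- zscore_matrix(m, (2 * 6 - 1) * m$genome$bin_size)
    tr <- separation_score(z, ws)
    bc <- call_boundaries(tr, z)
    .fixtures[[key]] <- list(z = z, track = tr, calls = bc,
                             tads = domains_from_boundaries(bc, m$genome))
  }
  .fixtures[[key]]
}

# TRUE for each (chrom, pos) with some b-entry on the same chrom within tol
near_any <- function(chrom, pos, b_chrom, b_pos, tol) {
  vapply(seq_along(pos), function(r) {
    cand <- b_pos[b_chrom == chrom[r]]
    length(cand) > 0 && min(abs(cand - pos[r])) <= tol
  }, logical(1))
}

# tiny hand-made contact matrix from a dense symmetric matrix
cm_from_dense <- function(x, bin_size = 1) {
  n <- nrow(x)
  g <- genome_spec(c(chrA = n * bin_size), bin_size)
  idx <- which(upper.tri(x, diag = TRUE) & x != 0, arr.ind = TRUE)
  contact_matrix(g, idx[, 1] - 1L, idx[, 2] - 1L, x[idx])
}

# minimal tad_set from explicit domain sizes on one chromosome
tadset_from_sizes <- function(sizes, genome = NULL) {
  ends <- cumsum(sizes)
  starts <- c(0, ends[-length(ends)])
  if (is.null(genome)) genome <- genome_spec(c(chr1 = ends[length(ends)]), 1)
  structure(list(genome = genome,
                 domains = data.frame(chrom = "chr1", start = starts,
                                      end = ends, size = sizes,
                                      stringsAsFactors = FALSE),
                 boundaries = data.frame(
                   chrom = rep("chr1", length(ends) - 1),
                   pos = ends[-length(ends)],
                   stringsAsFactors = FALSE)),
            class = "tad_set")
}

# simulated bundle written to disk once per run (pipeline + acceptance)
bundle_dir <- function() {
  if (is.null(.fixtures$bundle_dir)) {
    d <- file.path(tempdir(), "chromoshift-bundle")
    simulate_bundle(sim_config(seed = 1), dir = d)
    .fixtures$bundle_dir <- d
  }
  .fixtures$bundle_dir
}

write_run_config <- function(dir, out_dir, with_atac = TRUE, seed = 1) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    matrices = list(
      cond1_bins = file.path(dir, "cond1_5kb_abs.bed"),
      cond1_matrix = file.path(dir, "cond1_5kb.matrix"),
      cond2_bins = file.path(dir, "cond2_5kb_abs.bed"),
      cond2_matrix = file.path(dir, "cond2_5kb.matrix")),
    annotations = list(genes = file.path(dir, "genes.bed"),
                       tes = file.path(dir, "tes.bed")),
    counts = list(rna = file.path(dir, "rna_counts.tsv"),
                  te = file.path(dir, "te_counts.tsv")))
  if (with_atac)
    cfg$atac <- list(peaks = file.path(dir, "peaks.bed"),
                     counts = file.path(dir, "atac_counts.tsv"))
  path <- file.path(dir, if (with_atac) "run.yaml" else "run_noatac.yaml")
  yaml::write_yaml(cfg, path)
  path
}
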