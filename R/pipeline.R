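# End-to-end orchestration: a YAML run config is validated, every stage
# (compartments -> TADs -> contact classes -> expression -> ATAC) is
# executed in order, and a machine-readable report directory (one TSV
# per panel + a JSON index) is written. Fixed seed => byte-identical
# report.

default_thresholds <- function() {
  list(contact_threshold = 20000, delta = 0.01, q = 0.05,
       switch_epsilon = 0.01, de_lfc = 1, de_p = 0.01, peak_p = 0.05,
       promoter_bp = 1000, compartment_bin = 100000,
       min_tad_size_bins = 3, boundary_tol_bins = 1)
}

#' Validate a pipeline run configuration
#'
#' Reads a YAML config (or takes a list), fills threshold defaults,
#' and collects every violation instead of stopping at the first.
#'
#' @param cfg path to a YAML file or a config list.
#' @return the normalized config list, or an error listing every
#'   violation (field paths included).
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  errs <- character(0)
  need <- function(path) {
    parts <- strsplit(path, "\\$")[[1]]
    x <- cfg
    for (p in parts) {
      if (!is.list(x) || is.null(x[[p]])) return(NULL)
      x <- x[[p]]
    }
    x
  }
  req_files <- c("matrices$cond1_bins", "matrices$cond1_matrix",
                 "matrices$cond2_bins", "matrices$cond2_matrix",
                 "annotations$genes", "counts$rna")
  for (f in req_files) {
    v <- need(f)
    if (is.null(v)) errs <- c(errs, paste0("missing required field: ", f))
    else if (!file.exists(v)) errs <- c(errs, paste0(f, ": file not found: ", v))
  }
  opt_files <- c("annotations$tes", "counts$te", "atac$peaks", "atac$counts")
  for (f in opt_files) {
    v <- need(f)
    if (!is.null(v) && !file.exists(v))
      errs <- c(errs, paste0(f, ": file not found: ", v))
  }
  if (is.null(need("out_dir"))) errs <- c(errs, "missing required field: out_dir")
  if (is.null(need("seed"))) cfg$seed <- 1L
  thr <- utils::modifyList(default_thresholds(),
                           if (is.list(need("thresholds"))) cfg$thresholds
                           else list())
  rng <- list(contact_threshold = c(1, Inf), delta = c(0, 1), q = c(0, 1),
              switch_epsilon = c(0, 1), de_lfc = c(0, Inf), de_p = c(0, 1),
              peak_p = c(0, 1), promoter_bp = c(1, Inf),
              compartment_bin = c(1, Inf), min_tad_size_bins = c(1, Inf),
              boundary_tol_bins = c(0, Inf))
  for (nm in names(rng)) {
    v <- thr[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < rng[[nm]][1] ||
        v > rng[[nm]][2])
      errs <- c(errs, sprintf("thresholds$%s: value %s outside [%g, %g]",
                              nm, paste(v, collapse = ","),
                              rng[[nm]][1], rng[[nm]][2]))
  }
  if (length(errs))
    stop("invalid config:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  cfg$thresholds <- thr
  cfg
}

log_stage <- function(con, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

write_panel <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  con <- file(path, "w")
  writeLines(format_header(), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paste0(name, ".tsv")
}

#' Run the full comparative pipeline
#'
#' Executes compartment calling and switch classification, TAD calling
#' and comparison, contact-class and decay analysis, expression
#' integration, and (when ATAC inputs are present) accessibility
#' integration. Results are written to `out_dir` as one TSV per report
#' panel plus `index.json`; missing optional inputs skip their panels
#' with a logged warning, missing required inputs abort.
#'
#' @param cfg config list or YAML path (see [validate_config()]).
#' @return invisibly, the report index (panel name -> file).
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  thr <- cfg$thresholds
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logcon), add = TRUE)
  index <- list()

  log_stage(logcon, "load", "reading contact matrices")
  m1 <- read_matrix(cfg$matrices$cond1_bins, cfg$matrices$cond1_matrix)
  m2 <- read_matrix(cfg$matrices$cond2_bins, cfg$matrices$cond2_matrix)
  if (!same_genome(m1$genome, m2$genome))
    stop("condition matrices disagree on the genome")
  genes <- read_intervals(cfg$annotations$genes, kind = "gene",
                          genome = m1$genome)
  mc1 <- aggregate_matrix(m1, thr$compartment_bin)
  mc2 <- aggregate_matrix(m2, thr$compartment_bin)

  log_stage(logcon, "compartments", "PCA compartment calling")
  p1 <- call_compartments(mc1, genes)
  p2 <- call_compartments(mc2, genes)
  sw <- classify_switches(p1, p2, epsilon_factor = thr$switch_epsilon)
  write_bedgraph(signal_track(p1$genome, p1$pc1),
                 file.path(out_dir, "pc1_cond1.bedGraph"))
  write_bedgraph(signal_track(p2$genome, p2$pc1),
                 file.path(out_dir, "pc1_cond2.bedGraph"))
  index$compartment_switch_counts <- write_panel(data.frame(
    class = names(sw$bin_counts), n_bins = as.integer(sw$bin_counts),
    n_segments = as.integer(table(factor(sw$segments$class,
                             levels = names(sw$bin_counts))))),
    out_dir, "compartment_switch_counts")
  log_stage(logcon, "compartments",
            sprintf("switching bins: %d",
                    sum(sw$bin_counts[c("A-B", "B-A")])))

  log_stage(logcon, "tads", "separation score and boundary calling")
  ws <- m1$genome$bin_size * (3:6)
  zmax <- (2 * max(ws) / m1$genome$bin_size - 1) * m1$genome$bin_size
  call_tads <- function(m) {
    z <- zscore_matrix(m, zmax)
    tr <- separation_score(z, ws)
    bc <- call_boundaries(tr, z, thr$delta, thr$q)
    domains_from_boundaries(bc, m$genome,
                            min_size = thr$min_tad_size_bins *
                              m$genome$bin_size)
  }
  t1 <- call_tads(m1)
  t2 <- call_tads(m2)
  venn <- shared_tads(t1, t2, fraction = 0.8)
  index$tad_venn <- write_panel(data.frame(
    n_shared = venn$n_shared, n_cond1_only = venn$n_set1_only,
    n_cond2_only = venn$n_set2_only), out_dir, "tad_venn")
  index$tad_sizes <- write_panel(compare_tad_sizes(t1, t2, p1),
                                 out_dir, "tad_sizes")
  lost <- lost_boundaries(t1, t2, sw, tol = thr$boundary_tol_bins)
  log_stage(logcon, "tads",
            sprintf("%d + %d domains, %d lost boundaries",
                    nrow(t1$domains), nrow(t2$domains), lost$n_lost))

  log_stage(logcon, "interactions", "contact classes and decay change")
  cc1 <- classify_contacts(m1, thr$contact_threshold)
  cc2 <- classify_contacts(m2, thr$contact_threshold)
  index$contact_classes <- write_panel(data.frame(
    condition = rep(c("cond1", "cond2"), each = 3),
    class = rep(names(cc1$counts), 2),
    count = c(cc1$counts, cc2$counts),
    fraction = c(cc1$fractions, cc2$fractions)), out_dir,
    "contact_classes")
  index$decay_curve <- write_panel(decay_change(m1, m2), out_dir,
                                   "decay_curve")

  log_stage(logcon, "expression", "differential expression + integration")
  rna <- read_counts(cfg$counts$rna)
  gl <- stats::setNames(genes$end - genes$start, genes$id)
  es <- differential_expression(rna, gl, lfc_threshold = thr$de_lfc,
                                p_threshold = thr$de_p)
  shift <- switch_region_shift(es, sw, genes)
  shift$feature_kind <- "gene"
  if (!is.null(cfg$annotations$tes) && !is.null(cfg$counts$te)) {
    tes <- read_intervals(cfg$annotations$tes, kind = "TE",
                          genome = m1$genome)
    tstats <- differential_expression(read_counts(cfg$counts$te),
      stats::setNames(tes$end - tes$start, tes$id),
      lfc_threshold = thr$de_lfc, p_threshold = thr$de_p)
    tshift <- switch_region_shift(tstats, sw, tes)
    tshift$feature_kind <- "TE"
    shift <- rbind(shift, tshift)
  }
  index$switch_expression <- write_panel(shift, out_dir,
                                         "switch_expression")
  coreg <- tad_coregulation(es, t1, genes, seed = cfg$seed)
  index$tad_sd <- write_panel(data.frame(
    n_tads = coreg$n_tads, n_random = coreg$n_random,
    median_tad_sd = stats::median(coreg$tad_sd),
    median_random_sd = stats::median(coreg$random_sd),
    pvalue = coreg$pvalue), out_dir, "tad_sd")

  if (!is.null(cfg$atac$peaks) && !is.null(cfg$atac$counts)) {
    log_stage(logcon, "atac", "accessibility integration")
    peaks <- read_intervals(cfg$atac$peaks, kind = "peak",
                            genome = m1$genome)
    acounts <- read_counts(cfg$atac$counts)
    ps <- differential_peaks(acounts, peaks, p_threshold = thr$peak_p)
    sig <- peak_signal(peaks, acounts)
    comp_label <- p1$label[bin_of(genes$chrom, midpoints(genes),
                                  p1$genome) + 1L]
    prof <- metagene_profile(sig, genes, m1$genome, strata = comp_label)
    index$atac_profiles <- write_panel(prof$profile, out_dir,
                                       "atac_profiles")
    fa <- fisher_association(peaks, ps$differential, sw$segments)
    index$fisher_tables <- write_panel(data.frame(
      a_diff_in = fa$table[1, 1], b_diff_out = fa$table[1, 2],
      c_nondiff_in = fa$table[2, 1], d_nondiff_out = fa$table[2, 2],
      odds_ratio = fa$odds_ratio, pvalue = fa$pvalue),
      out_dir, "fisher_tables")
    # condition-2 domains that swallowed a lost boundary vs the rest
    d2 <- t2$domains
    has_loss <- vapply(seq_len(nrow(d2)), function(r) {
      any(lost$lost$chrom == d2$chrom[r] & lost$lost$pos > d2$start[r] &
            lost$lost$pos < d2$end[r])
    }, logical(1))
    index$boundary_loss_peaks <- write_panel(
      boundary_loss_peak_counts(peaks, ps$differential,
                                d2[has_loss, , drop = FALSE],
                                d2[!has_loss, , drop = FALSE]),
      out_dir, "boundary_loss_peaks")
  } else {
    log_stage(logcon, "atac", "no ATAC inputs; skipping optional panels")
  }

  meta <- list(
    version = as.character(utils::packageVersion("chromoshift")),
    seed = cfg$seed,
    panels = index)
  jsonlite::write_json(meta, file.path(out_dir, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage(logcon, "done", sprintf("%d panels written", length(index)))
  invisible(index)
}
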