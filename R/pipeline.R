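stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full introgression analysis pipeline
#'
#' Orchestrates QC, windowing, the per-recipient haplotype-similarity scan,
#' control-population exclusion, region merging, genome-fraction and
#' sharing summaries, the runs test, and (optionally) the gene-density
#' correlation, IBD summarization and the XP-EHH selection scan with
#' introgression/selection overlap ratios.
#'
#' @param haps a [HaplotypeSet], or `NULL` to load from `vcf`.
#' @param popmap a [PopulationMap], or `NULL` to load from `popmap_path`.
#' @param vcf,popmap_path input paths used when the in-memory objects are
#'   not supplied.
#' @param k window size in SNPs.
#' @param B permutations per window.
#' @param alpha candidate p-value threshold.
#' @param seed integer seed covering every stochastic stage.
#' @param qc apply [qc_filter_sites()] first.
#' @param maf_min,call_rate_min QC thresholds.
#' @param recipients recipient population labels; defaults to every
#'   population with role `recipient`.
#' @param control control population label; defaults to the population with
#'   role `control` if one exists, else no exclusion.
#' @param selection run the XP-EHH scan per recipient (ancestor proxy as
#'   reference).
#' @param annotation gene [RegionSet] or GFF3 path for the gene-density
#'   correlation (`NULL` to skip).
#' @param ibd_segments IBD segment data.frame or path (`NULL` to skip).
#' @param gene_bin bin width for the gene-density correlation.
#' @param out_dir optional output directory for TSV/BED files.
#' @return list with `windows`, per-recipient `scans`, `candidates`
#'   (post-exclusion flags), `regions`, `summary` (one row per recipient),
#'   `sharing`, `selection`, `ibd`, `qc_report`.
#' @export
run_pipeline <- function(haps = NULL, popmap = NULL, vcf = NULL,
                         popmap_path = NULL, k = 5, B = 1000, alpha = 0.001,
                         seed = NULL, qc = TRUE, maf_min = 0.05,
                         call_rate_min = 0.95, recipients = NULL,
                         control = NULL, selection = FALSE,
                         annotation = NULL, ibd_segments = NULL,
                         gene_bin = 1e6, out_dir = NULL) {
  stage("load", {
    if (is.null(haps)) {
      if (is.null(vcf)) stop("either haps or vcf must be given")
      loaded <- read_phased_vcf(vcf, popmap_path)
      haps <- loaded$haps
      popmap <- loaded$popmap
    }
    stopifnot(inherits(haps, "HaplotypeSet"),
              inherits(popmap, "PopulationMap"))
    role_population(popmap, "ancestor_proxy")
    role_population(popmap, "donor")
    if (is.null(recipients))
      recipients <- role_population(popmap, "recipient", several = TRUE)
    if (is.null(control) && any(popmap$role == "control"))
      control <- role_population(popmap, "control")
  })
  if (!is.null(seed)) set.seed(seed)

  qc_report <- NULL
  if (qc) stage("qc", {
    f <- qc_filter_sites(haps, maf_min, call_rate_min)
    haps <- f$haps
    qc_report <- f$report
  })

  wi <- stage("windows", build_windows(haps$sites, k))

  scans <- list()
  stage("scan", for (p in recipients)
    scans[[p]] <- scan_introgression(haps, popmap, B = B, alpha = alpha,
                                     recipient = p, window_index = wi))
  control_flags <- rep(FALSE, nrow(wi))
  if (!is.null(control)) stage("control_scan", {
    cs <- scan_introgression(haps, popmap, B = B, alpha = alpha,
                             recipient = control, window_index = wi)
    control_flags <- call_candidates(cs, alpha)
    scans[[control]] <- cs
  })

  candidates <- lapply(recipients, function(p)
    exclude_control_overlap(call_candidates(scans[[p]], alpha),
                            control_flags))
  names(candidates) <- recipients
  regions <- lapply(candidates, merge_candidate_regions, window_index = wi)

  sharing <- if (length(recipients) >= 2L)
    stage("sharing", sharing_summary(candidates)) else NULL

  genes <- NULL
  if (!is.null(annotation)) stage("annotation", {
    genes <- if (is.character(annotation)) read_gene_annotation(annotation)
      else annotation
  })
  ibd <- NULL
  if (!is.null(ibd_segments)) stage("ibd", {
    segs <- if (is.character(ibd_segments)) read_ibd_segments(ibd_segments)
      else ibd_segments
    ibd <- summarize_ibd(segs, popmap)
  })

  sel <- NULL
  if (selection) stage("selection", {
    anc <- role_population(popmap, "ancestor_proxy")
    sel <- lapply(recipients, function(p)
      xpehh_scan(haps, popmap, anc, p, window_index = wi))
    names(sel) <- recipients
  })

  donor_pop <- role_population(popmap, "donor")
  summary_rows <- lapply(recipients, function(p) {
    fl <- candidates[[p]]
    fr <- introgression_fraction(fl, wi)
    rt <- if (sum(fl) > 0 && sum(!fl) > 0)
      runs_test(fl, wi$chrom) else NULL
    row <- data.frame(population = p,
                      n_candidate_windows = sum(fl),
                      introgression_pct_bp = fr$bp_percent,
                      introgression_pct_windows = fr$window_percent,
                      runs_Z = if (is.null(rt)) NA_real_ else rt$Z)
    if (!is.null(ibd)) {
      hit <- ibd[(ibd$pop_a == p & ibd$pop_b == donor_pop) |
                   (ibd$pop_b == p & ibd$pop_a == donor_pop), ]
      row$ibd_mb_per_pair <- if (nrow(hit)) hit$mb_per_pair[1L] else 0
    }
    if (!is.null(genes)) {
      gd <- tryCatch(gene_density_correlation(fl, genes, wi, gene_bin),
                     error = function(e) NULL)
      row$gene_density_r <- if (is.null(gd)) NA_real_ else gd$r
      row$gene_density_p <- if (is.null(gd)) NA_real_ else gd$p
    }
    if (!is.null(sel)) {
      ov <- overlap_stats(fl, sel[[p]]$calls$selected, wi)
      row$introgression_pct_of_selected <- ov$introgressed_of_selected
      row$selected_pct_of_genome <- ov$selected_of_genome
      row$selected_pct_of_introgressed <- ov$selected_of_introgressed
    }
    row
  })
  summary <- do.call(rbind, summary_rows)

  bundle <- list(windows = wi, scans = scans, candidates = candidates,
                 regions = regions, summary = summary, sharing = sharing,
                 selection = sel, ibd = ibd, qc_report = qc_report)

  if (!is.null(out_dir)) stage("write", {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    for (p in names(scans))
      tsv(scans[[p]], paste0("scan_", p, ".tsv"))
    for (p in recipients)
      write_regions(regions[[p]],
                    file.path(out_dir, paste0("introgression_", p, ".bed")))
    tsv(summary, "summary.tsv")
    if (!is.null(sharing)) tsv(sharing, "sharing.tsv")
    if (!is.null(ibd)) tsv(ibd, "ibd_sharing.tsv")
    if (!is.null(sel)) for (p in recipients) {
      tsv(sel[[p]]$records, paste0("xpehh_", p, ".tsv"))
      tsv(sel[[p]]$calls, paste0("selection_calls_", p, ".tsv"))
    }
  })
  bundle
}

#' Introgression fraction across a window-size sweep
#'
#' Repeats the scan for each window size in `k_list` and reports the
#' post-exclusion introgressed genome fraction per recipient population.
#'
#' @inheritParams run_pipeline
#' @param k_list window sizes in SNPs (all within 2..20).
#' @return data.frame with columns `k`, `population`,
#'   `introgression_pct_bp`, `introgression_pct_windows`.
#' @export
window_size_sweep <- function(haps, popmap, k_list = 2:10, B = 1000,
                              alpha = 0.001, seed = NULL, recipients = NULL,
                              control = NULL, qc = TRUE) {
  if (any(k_list < 2 | k_list > 20))
    stop("window sizes must be within 2..20")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(k_list, function(k) {
    res <- run_pipeline(haps, popmap, k = k, B = B, alpha = alpha,
                        recipients = recipients, control = control, qc = qc)
    cbind(k = k, res$summary[, c("population", "introgression_pct_bp",
                                 "introgression_pct_windows")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
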