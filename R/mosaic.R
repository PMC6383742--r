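#' Fast haplotype-mosaic fixture generator
#'
#' Builds a three-population phased dataset with exactly controlled donor
#' truth, without forward simulation.  Ancestor-proxy and donor allele
#' frequencies diverge by a Balding-Nichols drift model with parameter
#' `divergence` (F = 0 makes all three populations exchangeable);
#' haplotypes are drawn site-independently from their population
#' frequencies.  Recipient haplotypes follow the ancestor-pool frequencies
#' except inside planted donor tracts — contiguous site blocks covering
#' `donor_fraction` of the sites — where carriers draw from the donor
#' frequencies instead.
#'
#' @param n_anc,n_rec,n_donor diploid sample sizes.
#' @param n_sites number of SNPs (positions `spacing` bp apart on one
#'   chromosome).
#' @param donor_fraction fraction of sites covered by planted donor tracts.
#' @param divergence Balding-Nichols F between ancestor and donor pools.
#' @param seed optional integer seed.
#' @param tract_sites sites per planted tract (the last tract may be
#'   shorter).
#' @param carrier_fraction fraction of recipient haplotypes carrying each
#'   tract (1 = all).
#' @param spacing bp between adjacent sites.
#' @param n_out diploids in an optional outgroup population (`OUT`, role
#'   `outgroup`), drawn with divergence `out_divergence` from the ancestral
#'   frequencies; 0 omits it.  Useful for D-statistic calibration, where an
#'   exchangeable (ancestor, recipient) pair plus a diverged donor and
#'   outgroup give a well-conditioned null.
#' @param out_divergence Balding-Nichols F for the outgroup pool.
#' @return list with `haps`, `popmap` (roles ancestor_proxy, recipient,
#'   donor) and `truth` (class `SimTruth`, as in [simulate_forward()]).
#' @export
mosaic_generator <- function(n_anc = 50, n_rec = 50, n_donor = 50,
                             n_sites = 1000, donor_fraction = 0,
                             divergence = 0.3, seed = NULL,
                             tract_sites = 100, carrier_fraction = 1,
                             spacing = 1000, n_out = 0,
                             out_divergence = 0.5) {
  if (donor_fraction < 0 || donor_fraction > 1)
    stop("donor_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p_anc <- stats::runif(n_sites, 0.05, 0.95)
  p_don <- if (divergence > 0) {
    F <- divergence
    stats::rbeta(n_sites, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  } else p_anc

  n_target <- round(donor_fraction * n_sites)
  tract_cols <- integer()
  tract_bounds <- NULL
  if (n_target >= 1) {
    tract_sites <- min(tract_sites, n_target)
    n_tracts <- ceiling(n_target / tract_sites)
    sizes <- rep(tract_sites, n_tracts)
    sizes[n_tracts] <- n_target - tract_sites * (n_tracts - 1)
    # place tracts without overlap: choose starts in shuffled spaced slots
    slots <- seq(1L, n_sites - tract_sites + 1L, by = tract_sites)
    if (length(slots) < n_tracts)
      stop("donor_fraction too large for tract_sites")
    starts <- sort(sample(slots, n_tracts))
    tract_bounds <- data.frame(first = starts, last = starts + sizes - 1L)
    tract_cols <- unlist(mapply(seq, starts, starts + sizes - 1L,
                                SIMPLIFY = FALSE))
    if (n_target < tract_sites)
      warning("planted donor material covers fewer sites than one typical ",
              "scan window span; detection may be unstable")
  }

  draw <- function(n_hap, p)
    matrix(stats::rbinom(n_hap * length(p), 1L, rep(p, each = n_hap)),
           nrow = n_hap)
  A <- draw(2L * n_anc, p_anc)
  D <- draw(2L * n_donor, p_don)
  R <- draw(2L * n_rec, p_anc)
  tracts <- NULL
  if (length(tract_cols)) {
    for (t in seq_len(nrow(tract_bounds))) {
      cols <- seq(tract_bounds$first[t], tract_bounds$last[t])
      carriers <- if (carrier_fraction >= 1) seq_len(2L * n_rec) else
        sample(2L * n_rec, max(1L, round(carrier_fraction * 2L * n_rec)))
      R[carriers, cols] <-
        draw(length(carriers), p_don[cols])
      tracts <- rbind(tracts, data.frame(
        hap = sort(carriers), chrom = "1",
        start = (tract_bounds$first[t] - 1L) * spacing,
        end = tract_bounds$last[t] * spacing))
    }
  }
  if (is.null(tracts))
    tracts <- data.frame(hap = integer(), chrom = character(),
                         start = numeric(), end = numeric())

  sites <- data.frame(chrom = "1", pos = spacing * seq_len(n_sites),
                      id = paste0("m", seq_len(n_sites)),
                      ref = "A", alt = "T")
  samples <- c(paste0("ANC_", seq_len(n_anc)),
               paste0("REC_", seq_len(n_rec)),
               paste0("DON_", seq_len(n_donor)))
  # consecutive row pairs within each pool form one diploid sample
  alleles <- rbind(A, R, D)
  roles <- c(ANC = "ancestor_proxy", REC = "recipient", DON = "donor")
  pops <- rep(c("ANC", "REC", "DON"), times = c(n_anc, n_rec, n_donor))
  if (n_out > 0) {
    Fo <- out_divergence
    p_out <- stats::rbeta(n_sites, p_anc * (1 - Fo) / Fo,
                          (1 - p_anc) * (1 - Fo) / Fo)
    alleles <- rbind(alleles, draw(2L * n_out, p_out))
    samples <- c(samples, paste0("OUT_", seq_len(n_out)))
    pops <- c(pops, rep("OUT", n_out))
    roles <- c(roles, OUT = "outgroup")
  }
  popmap <- PopulationMap(samples, pops, roles)
  haps <- HaplotypeSet(alleles, sites, samples, sort = FALSE)
  genome_length <- n_sites * spacing
  frac <- if (nrow(tracts))
    100 * sum(tracts$end - tracts$start) / (2 * n_rec * genome_length)
  else 0
  truth <- structure(list(tracts = tracts, true_donor_fraction = frac,
                          n_recipient_haps = 2L * n_rec,
                          benefit_bp = numeric(),
                          genome_length = genome_length),
                     class = "SimTruth")
  list(haps = haps, popmap = popmap, truth = truth)
}

#' Window-level evaluation of a scan against simulated truth
#'
#' A window counts as truly introgressed when at least `bp_fraction` of its
#' span is donor-origin in at least `hap_fraction` of the recipient
#' haplotypes.  Precision and recall are computed window-wise; the
#' estimated genome fraction (bp-based) is compared with the truth
#' fraction.
#'
#' @param candidates logical per-window candidate flags (or a scan
#'   data.frame with a `candidate` column).
#' @param truth a `SimTruth`.
#' @param window_index the `WindowIndex` the scan used.
#' @param bp_fraction minimum donor fraction of a window's span (per
#'   haplotype) for that haplotype to count as a carrier.
#' @param hap_fraction minimum fraction of recipient haplotypes carrying
#'   the window.
#' @return list with `precision` (NA when nothing was called), `recall`
#'   (NA when no window is true), `n_true_windows`, `truth_flags`,
#'   `estimated_fraction`, `true_fraction` (both bp percent).
#' @export
evaluate_scan <- function(candidates, truth, window_index,
                          bp_fraction = 0.5, hap_fraction = 0.05) {
  if (is.data.frame(candidates)) candidates <- candidates$candidate
  W <- nrow(window_index)
  if (length(candidates) != W)
    stop("flags do not match the window index")
  n_hap <- truth$n_recipient_haps
  carriers <- matrix(0, nrow = n_hap, ncol = W)
  tr <- truth$tracts
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      ov_start <- pmax(window_index$start_bp, tr$start[i])
      ov_end <- pmin(window_index$end_bp, tr$end[i])
      ov <- pmax(0, ov_end - ov_start) *
        (window_index$chrom == tr$chrom[i])
      carriers[tr$hap[i], ] <- carriers[tr$hap[i], ] + ov
    }
  }
  span <- window_index$end_bp - window_index$start_bp
  is_carrier <- sweep(carriers, 2L, span, "/") >= bp_fraction
  truth_flags <- colMeans(is_carrier) >= hap_fraction
  tp <- sum(candidates & truth_flags)
  precision <- if (sum(candidates)) tp / sum(candidates) else NA_real_
  recall <- if (sum(truth_flags)) tp / sum(truth_flags) else NA_real_
  list(precision = precision, recall = recall,
       n_true_windows = sum(truth_flags), truth_flags = truth_flags,
       estimated_fraction = introgression_fraction(candidates,
                                                   window_index)$bp_percent,
       true_fraction = truth$true_donor_fraction)
}

#' Toy gene annotation generator
#'
#' Places `n_genes` gene intervals on a single chromosome, uniformly or
#' clustered (genes concentrated in a subset of 1 Mb neighbourhoods), and
#' optionally writes them as GFF3.
#'
#' @param n_genes number of genes (0 gives an empty set).
#' @param genome_length chromosome length in bp.
#' @param clustering 0 for uniform placement; larger values concentrate
#'   genes into fewer neighbourhoods (fraction `1 - clustering` of the
#'   genome receives all genes).
#' @param seed optional integer seed.
#' @param gene_length gene span in bp.
#' @param path optional GFF3 output path.
#' @return a [RegionSet] of gene intervals.
#' @export
toy_annotation <- function(n_genes, genome_length = 1e7, clustering = 0,
                           seed = NULL, gene_length = 10000, path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_genes < 1) {
    rs <- RegionSet(label = "genes")
  } else {
    usable <- genome_length * (1 - min(max(clustering, 0), 0.95))
    starts <- sort(round(stats::runif(n_genes, 0, usable - gene_length)))
    starts <- pmin(starts, genome_length - gene_length)
    rs <- RegionSet(rep("1", n_genes), starts, starts + gene_length,
                    label = "genes")
  }
  if (!is.null(path)) {
    lines <- c("##gff-version 3",
               if (nrow(rs))
                 sprintf("1\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=gene%d",
                         rs$start + 1L, rs$end, seq_len(nrow(rs))))
    writeLines(lines, path)
  }
  rs
}
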