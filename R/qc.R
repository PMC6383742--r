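maf_from_dosage <- function(g) {
  # g: samples x sites dosage matrix (0/1/2, NA allowed)
  n_called <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(p, 1 - p)
  maf[n_called == 0L] <- NA_real_
  maf
}

#' Site quality-control filter
#'
#' Removes sites with minor allele frequency below `maf_min` or genotype
#' call rate below `call_rate_min`, computed across all samples.  Both
#' thresholds follow common SNP-chip practice (MAF >= 0.05, call rate >=
#' 95%).  Accepts either a diploid dosage matrix (samples x sites, 0/1/2,
#' `NA` for missing) or a [HaplotypeSet] (which, being imputed, always has
#' call rate 1).
#'
#' @param x dosage matrix or `HaplotypeSet`.
#' @param maf_min minimum minor allele frequency (sites with MAF strictly
#'   below are removed).
#' @param call_rate_min minimum fraction of non-missing genotypes.
#' @return list with `keep` (logical per site), `report` (counts removed per
#'   filter) and, for a `HaplotypeSet` input, `haps` (the filtered set).
#' @export
qc_filter_sites <- function(x, maf_min = 0.05, call_rate_min = 0.95) {
  is_haps <- inherits(x, "HaplotypeSet")
  g <- if (is_haps) genotype_matrix(x) else as.matrix(x)
  call_rate <- colSums(!is.na(g)) / nrow(g)
  maf <- maf_from_dosage(g)
  fail_maf <- is.na(maf) | maf < maf_min
  fail_cr <- call_rate < call_rate_min
  keep <- !fail_maf & !fail_cr
  if (!any(keep)) stop("no sites survive QC")
  report <- c(n_input = ncol(g), n_fail_maf = sum(fail_maf),
              n_fail_call_rate = sum(fail_cr), n_kept = sum(keep))
  out <- list(keep = keep, report = report)
  if (is_haps) out$haps <- subset_haps(x, sites = which(keep))
  out
}

#' Proportion of polymorphic loci within a population
#'
#' A site counts as polymorphic when its minor allele frequency within the
#' population exceeds 0.05.  The within-population frequency is computed on
#' the population slice only, so sites monomorphic genome-wide but variable
#' locally still count.
#'
#' @param haps a [HaplotypeSet] (or dosage matrix).
#' @param popmap a [PopulationMap]; required for `HaplotypeSet` input.
#' @param population population label to slice.
#' @param maf_threshold within-population MAF above which a site is
#'   polymorphic.
#' @return fraction in `[0, 1]`.
#' @export
proportion_polymorphic <- function(haps, popmap = NULL, population = NULL,
                                   maf_threshold = 0.05) {
  if (inherits(haps, "HaplotypeSet")) {
    if (is.null(popmap) || is.null(population))
      stop("popmap and population required for HaplotypeSet input")
    g <- genotype_matrix(subset_haps(haps, pop_samples(popmap, population)))
  } else g <- as.matrix(haps)
  if (!nrow(g)) stop("empty population")
  maf <- maf_from_dosage(g)
  mean(!is.na(maf) & maf > maf_threshold)
}
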