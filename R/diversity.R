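#' Detect runs of homozygosity in one sample
#'
#' Scans an ordered per-chromosome genotype vector for maximal runs that
#' contain at most `max_het` heterozygous and `max_missing` missing calls.
#' A run qualifies as a ROH segment when it has at least `min_snps` SNPs
#' *or* spans at least `min_length` bp.  The scan is greedy left-to-right:
#' each emitted run is extended as far as the het/missing budgets allow and
#' the next run starts after it, so reported segments never overlap.
#'
#' @param genotypes integer vector of diploid dosages (0/1/2; `NA` missing),
#'   ordered by position along one chromosome.
#' @param positions integer vector of bp positions, strictly increasing.
#' @param min_snps minimum SNP count for a qualifying run.
#' @param min_length minimum bp span for a qualifying run.
#' @param max_het maximum heterozygous calls allowed inside a run.
#' @param max_missing maximum missing calls allowed inside a run.
#' @return data.frame with columns `start`, `end` (bp, inclusive),
#'   `n_snps`, `n_het`, `n_missing`; zero rows if no run qualifies.
#' @export
detect_roh <- function(genotypes, positions, min_snps = 50,
                       min_length = 500000, max_het = 1, max_missing = 5) {
  m <- length(genotypes)
  if (length(positions) != m) stop("genotypes/positions length mismatch")
  if (m > 1L && any(diff(positions) <= 0)) stop("unsorted sites")
  het <- !is.na(genotypes) & genotypes == 1L
  mis <- is.na(genotypes)
  out <- list()
  i <- 1L
  while (i <= m) {
    n_het <- 0L; n_mis <- 0L; j <- i - 1L
    while (j < m) {
      nh <- n_het + (het[j + 1L]); nm <- n_mis + (mis[j + 1L])
      if (nh > max_het || nm > max_missing) break
      j <- j + 1L; n_het <- nh; n_mis <- nm
    }
    if (j < i) { i <- i + 1L; next }
    len <- positions[j] - positions[i] + 1L
    if ((j - i + 1L) >= min_snps || len >= min_length)
      out[[length(out) + 1L]] <-
        data.frame(start = positions[i], end = positions[j],
                   n_snps = j - i + 1L, n_het = n_het, n_missing = n_mis)
    i <- j + 1L
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), n_snps = integer(),
                      n_het = integer(), n_missing = integer()))
  do.call(rbind, out)
}

roh_for_sample <- function(haps, sample, ...) {
  g <- genotype_matrix(subset_haps(haps, sample))[1L, ]
  segs <- lapply(unique(haps$sites$chrom), function(ch) {
    sel <- haps$sites$chrom == ch
    df <- detect_roh(g[sel], haps$sites$pos[sel], ...)
    if (nrow(df)) cbind(chrom = ch, df) else NULL
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs))
    segs <- data.frame(chrom = character(), start = integer(),
                       end = integer(), n_snps = integer(),
                       n_het = integer(), n_missing = integer())
  segs
}

#' Haplotype diversity of one window
#'
#' Unbiased gene-diversity analogue on window haplotype frequencies:
#' `H = N / (N - 1) * (1 - sum(x_i^2))`, where `x_i` is the frequency of
#' the i-th distinct haplotype and `N` the number of haplotypes counted
#' (two per diploid individual).  `H` is 0 when all haplotypes are
#' identical and exactly 1 when all are distinct.
#'
#' @param hap_counts integer vector of counts of the distinct haplotypes.
#' @param N total number of haplotypes; defaults to `sum(hap_counts)`.
#' @return `H` in `[0, 1]`.
#' @export
haplotype_diversity <- function(hap_counts, N = sum(hap_counts)) {
  if (N < 2) stop("N must be at least 2")
  if (!isTRUE(all.equal(sum(hap_counts), N)))
    stop("counts do not sum to N")
  x <- hap_counts / N
  N / (N - 1) * (1 - sum(x^2))
}

#' Per-population diversity report
#'
#' Computes, for each population in the map: the proportion of polymorphic
#' loci (within-population MAF > 0.05), ROH summaries (mean segment length
#' and mean per-individual total, both in Mb), and mean window haplotype
#' diversity for each requested window size.
#'
#' @param haps a [HaplotypeSet].
#' @param popmap a [PopulationMap].
#' @param window_sizes integer vector of window sizes (SNPs) for H.
#' @param roh_args list of arguments passed to [detect_roh()].
#' @return data.frame with one row per population.
#' @export
diversity_report <- function(haps, popmap, window_sizes = c(2, 5, 10, 20),
                             roh_args = list()) {
  pops <- unique(popmap$population)
  rows <- lapply(pops, function(p) {
    samples <- pop_samples(popmap, p)
    sub <- subset_haps(haps, samples)
    pn <- proportion_polymorphic(haps, popmap, p)
    segs <- lapply(samples, function(s)
      do.call(roh_for_sample, c(list(haps = sub, sample = s), roh_args)))
    seg_lens <- unlist(lapply(segs, function(d) d$end - d$start + 1))
    per_ind_total <- vapply(segs, function(d)
      sum(d$end - d$start + 1), numeric(1))
    row <- data.frame(population = p, n = length(samples),
                      pn = pn,
                      roh_mean_segment_mb =
                        if (length(seg_lens)) mean(seg_lens) / 1e6 else 0,
                      roh_mean_total_mb = mean(per_ind_total) / 1e6)
    for (k in window_sizes) {
      wi <- build_windows(sub$sites, k)
      h <- vapply(seq_len(nrow(wi)), function(w) {
        cnt <- window_hap_counts(sub, wi, w)
        haplotype_diversity(cnt)
      }, numeric(1))
      row[[paste0("H_k", k)]] <- if (length(h)) mean(h) else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}
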