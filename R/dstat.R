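pop_freqs <- function(haps, popmap, population) {
  rows <- hap_rows(haps, pop_samples(popmap, population))
  colMeans(haps$alleles[rows, , drop = FALSE])
}

#' Four-taxon D-statistic from derived-allele frequencies
#'
#' Patterson-style frequency estimator on the ordered set (P1, P2, P3,
#' outgroup), with a delete-one block jackknife over contiguous site blocks
#' for the Z-score.  Site pattern terms are `BABA = p1 (1-p2) p3 (1-pO)`
#' and `ABBA = (1-p1) p2 p3 (1-pO)`; the statistic is
#' `D = sum(BABA - ABBA) / sum(BABA + ABBA)`.  With this orientation a
#' *negative* D (and Z) indicates excess derived-allele sharing between P2
#' and P3 (or between P1 and the outgroup) — i.e. gene flow between the
#' recipient (P2) and the donor (P3) when the ordering is (ancestor proxy,
#' recipient, donor, outgroup).  Monomorphic sites contribute 0 to both
#' sums, so their inclusion never changes D.
#'
#' @param f1,f2,f3 derived-allele frequency vectors (equal length, site
#'   order preserved for blocking).
#' @param fo outgroup derived-allele frequencies (0 everywhere when
#'   frequencies are already polarized to the ancestral state).
#' @param block_size sites per jackknife block (default 500).
#' @return list of class `dstat` with `D`, `Z`, `se`, `n_blocks`,
#'   `n_informative_sites`.
#' @export
d_stat_freqs <- function(f1, f2, f3, fo = 0, block_size = 500) {
  m <- length(f1)
  stopifnot(length(f2) == m, length(f3) == m)
  if (length(fo) == 1L) fo <- rep(fo, m)
  baba <- f1 * (1 - f2) * f3 * (1 - fo)
  abba <- (1 - f1) * f2 * f3 * (1 - fo)
  num <- baba - abba
  den <- baba + abba
  if (sum(den) <= 0) stop("no informative sites")
  D <- sum(num) / sum(den)
  blk <- (seq_len(m) - 1L) %/% block_size
  bn <- tapply(num, blk, sum)
  bd <- tapply(den, blk, sum)
  use <- bd > 0
  bn <- bn[use]; bd <- bd[use]
  g <- length(bn)
  if (g < 2L) {
    Z <- NA_real_; se <- NA_real_
  } else {
    Dj <- (sum(bn) - bn) / (sum(bd) - bd)
    se <- sqrt((g - 1) / g * sum((Dj - mean(Dj))^2))
    Z <- D / se
  }
  structure(list(D = D, Z = Z, se = se, n_blocks = g,
                 n_informative_sites = sum(den > 0)),
            class = "dstat")
}

#' @export
print.dstat <- function(x, ...) {
  cat(sprintf("D = %.4f, Z = %.3f (%d blocks, %d informative sites)\n",
              x$D, x$Z, x$n_blocks, x$n_informative_sites))
  invisible(x)
}

#' D-statistic for four populations of a HaplotypeSet
#'
#' Computes per-population derived-allele frequencies, polarizes them, and
#' calls [d_stat_freqs()].  When `outgroup` is a population label, its
#' consensus (major) allele defines the ancestral state; sites where the
#' outgroup is polymorphic above `outgroup_poly_max` are dropped (with a
#' message).  When `outgroup` is `NULL`, the REF allele is taken as
#' ancestral (appropriate for simulated data where REF encodes the
#' ancestral state) and the outgroup frequency is 0 everywhere.
#'
#' @param haps a [HaplotypeSet].
#' @param popmap a [PopulationMap].
#' @param p1,p2,p3 population labels in the test ordering (ancestor proxy,
#'   recipient, donor).
#' @param outgroup outgroup population label, or `NULL` (see above).
#' @param block_size jackknife block size in sites.
#' @param outgroup_poly_max maximum outgroup minor-allele frequency before
#'   a site is dropped.
#' @return a `dstat` result (see [d_stat_freqs()]).
#' @export
d_statistic <- function(haps, popmap, p1, p2, p3, outgroup = NULL,
                        block_size = 500, outgroup_poly_max = 0.1) {
  f1 <- pop_freqs(haps, popmap, p1)
  f2 <- pop_freqs(haps, popmap, p2)
  f3 <- pop_freqs(haps, popmap, p3)
  if (is.null(outgroup)) {
    fo <- rep(0, length(f1))
  } else {
    fo <- pop_freqs(haps, popmap, outgroup)
    poly <- pmin(fo, 1 - fo) > outgroup_poly_max
    if (any(poly)) {
      message("dropping ", sum(poly), " site(s) polymorphic in the outgroup")
      f1 <- f1[!poly]; f2 <- f2[!poly]; f3 <- f3[!poly]; fo <- fo[!poly]
    }
    flip <- fo > 0.5
    f1[flip] <- 1 - f1[flip]; f2[flip] <- 1 - f2[flip]
    f3[flip] <- 1 - f3[flip]; fo[flip] <- 1 - fo[flip]
  }
  d_stat_freqs(f1, f2, f3, fo, block_size = block_size)
}
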