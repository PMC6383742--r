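#' Pearson chi-square between two haplotype count tables
#'
#' Forms the 2 x H contingency table whose columns are the pooled distinct
#' haplotypes of the two populations and computes the Pearson statistic
#' `sum((A_i - T_i)^2 / T_i)` over all cells, with expected counts `T_i`
#' from the table marginals (homogeneity expectation).  Pooled-zero columns
#' are dropped; no continuity correction is applied (inference comes from
#' the permutation null, not the chi-square distribution).  Low chi-square
#' means the two populations carry similar haplotype spectra.
#'
#' @param countsA,countsB named integer vectors (haplotype -> count).
#' @return the chi-square statistic (>= 0).
#' @export
pairwise_chi2 <- function(countsA, countsB) {
  keys <- union(names(countsA), names(countsB))
  a <- numeric(length(keys)); names(a) <- keys
  b <- a
  a[names(countsA)] <- countsA
  b[names(countsB)] <- countsB
  chi2_from_counts(a, b)
}

# two count vectors over identical (aligned) categories
chi2_from_counts <- function(a, b) {
  totA <- sum(a); totB <- sum(b)
  if (totA <= 0 || totB <= 0) stop("both count tables must be non-empty")
  cj <- a + b
  keep <- cj > 0
  a <- a[keep]; b <- b[keep]; cj <- cj[keep]
  N <- totA + totB
  ea <- totA * cj / N
  eb <- totB * cj / N
  sum((a - ea)^2 / ea) + sum((b - eb)^2 / eb)
}

#' Delta chi-square for one window
#'
#' `delta = chi2(ancestor_proxy, recipient) - chi2(recipient, donor)`.
#' Positive values indicate that the recipient's haplotype spectrum in this
#' window resembles the donor more than the ancestor proxy — the signature
#' of donor-to-recipient introgression.
#'
#' @param counts named list population -> named count vector, as produced by
#'   [count_haplotypes()].
#' @param popmap a [PopulationMap] (defines which population holds which
#'   role), or `NULL` if `counts` is already named with roles
#'   `ancestor_proxy`, `recipient`, `donor`.
#' @param recipient recipient population label; defaults to the single
#'   population with role `recipient`.
#' @return list with `chi2_anc`, `chi2_donor`, `delta`.
#' @export
delta_chi2 <- function(counts, popmap = NULL, recipient = NULL) {
  if (is.null(popmap)) {
    anc <- "ancestor_proxy"; don <- "donor"
    if (is.null(recipient)) recipient <- "recipient"
  } else {
    anc <- role_population(popmap, "ancestor_proxy")
    don <- role_population(popmap, "donor")
    if (is.null(recipient)) recipient <- role_population(popmap, "recipient")
  }
  for (p in c(anc, recipient, don))
    if (is.null(counts[[p]]))
      stop("counts missing population '", p, "'")
  chi2_anc <- pairwise_chi2(counts[[anc]], counts[[recipient]])
  chi2_donor <- pairwise_chi2(counts[[recipient]], counts[[don]])
  list(chi2_anc = chi2_anc, chi2_donor = chi2_donor,
       delta = chi2_anc - chi2_donor)
}
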