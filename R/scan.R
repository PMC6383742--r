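#' Haplotype-similarity introgression scan
#'
#' For every non-overlapping k-SNP window, computes the Pearson chi-square
#' between the ancestor-proxy and recipient haplotype counts and between the
#' recipient and donor counts, their difference `delta = chi2_anc -
#' chi2_donor`, and an empirical p-value from a label permutation null
#' (`p = (n + 1) / (B + 1)` with `n` the number of permuted delta values at
#' or above the observed one).  The permutation unit is the individual —
#' both haplotypes move together — and the three population sizes are held
#' fixed.  Windows with `p < alpha` and `delta > 0` are flagged candidates.
#'
#' @param haps a [HaplotypeSet].
#' @param popmap a [PopulationMap] with roles `ancestor_proxy` and `donor`
#'   assigned (and `recipient` unless `recipient` is given).
#' @param k window size in SNPs (default 5).
#' @param B number of permutations (default 1000).
#' @param alpha candidate threshold on the empirical p-value.
#' @param seed optional integer seed (calls `set.seed`).
#' @param recipient population label scanned as the recipient; defaults to
#'   the single population with role `recipient`.  Pass the control
#'   population's label to produce the control scan used by
#'   [exclude_control_overlap()].
#' @param window_index optional precomputed `WindowIndex` (must derive from
#'   `haps$sites` with the same `k`).
#' @param early_stop if `TRUE`, a window's permutation loop stops as soon
#'   as enough permuted deltas have reached the observed one to rule out
#'   candidacy at `alpha`.  Candidate flags are unchanged; reported
#'   p-values for stopped windows become conservative anytime estimates
#'   based on the permutations actually run (`b_used`).
#' @return data.frame with one row per window: `window`, `chrom`,
#'   `start_bp`, `end_bp`, `chi2_anc`, `chi2_donor`, `delta`, `p_emp`,
#'   `candidate`; attributes `window_index`, `k`, `B`, `alpha`, `recipient`.
#' @export
scan_introgression <- function(haps, popmap, k = 5, B = 1000, alpha = 0.001,
                               seed = NULL, recipient = NULL,
                               window_index = NULL, early_stop = FALSE) {
  if (B < 1) stop("B must be at least 1")
  anc <- role_population(popmap, "ancestor_proxy")
  don <- role_population(popmap, "donor")
  if (is.null(recipient)) recipient <- role_population(popmap, "recipient")
  samples <- c(pop_samples(popmap, anc), pop_samples(popmap, recipient),
               pop_samples(popmap, don))
  grp <- rep(0:2, times = c(length(pop_samples(popmap, anc)),
                            length(pop_samples(popmap, recipient)),
                            length(pop_samples(popmap, don))))
  sub <- subset_haps(haps, samples)
  wi <- if (is.null(window_index)) build_windows(sub$sites, k) else
    window_index
  if (!nrow(wi)) stop("no complete windows: too few sites for k = ", k)
  codes <- encode_windows(sub, wi)
  M <- length(samples)
  code1 <- codes[seq(1L, 2L * M, 2L), , drop = FALSE]
  code2 <- codes[seq(2L, 2L * M, 2L), , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  # stopping a window once candidacy is impossible leaves flags identical
  max_exceed <- if (early_stop) max(1, ceiling(alpha * (B + 1) - 1)) else 0
  res <- .perm_scan_cpp(code1, code2, as.integer(grp), as.integer(B),
                        as.integer(max_exceed))
  p_emp <- (res$n_ge + 1) / (res$b_done + 1)
  out <- data.frame(window = wi$window, chrom = wi$chrom,
                    start_bp = wi$start_bp, end_bp = wi$end_bp,
                    chi2_anc = res$chi2_anc, chi2_donor = res$chi2_donor,
                    delta = res$delta, n_ge = res$n_ge, b_used = res$b_done,
                    p_emp = p_emp,
                    candidate = (res$n_ge + 1) / (B + 1) < alpha &
                      res$delta > 0)
  attr(out, "window_index") <- wi
  attr(out, "k") <- attr(wi, "k")
  attr(out, "B") <- B
  attr(out, "alpha") <- alpha
  attr(out, "recipient") <- recipient
  out
}

#' Permutation p-value for a single window
#'
#' Convenience wrapper around the scan kernel for one window.
#'
#' @inheritParams scan_introgression
#' @param window_index a `WindowIndex`.
#' @param window window number.
#' @return list with `delta`, `p_emp` and the permutation count `n_ge`.
#' @export
permutation_test <- function(haps, window_index, window, popmap, B = 1000,
                             seed = NULL, recipient = NULL) {
  wi1 <- window_index[window_index$window == window, , drop = FALSE]
  if (!nrow(wi1)) stop("no such window: ", window)
  attr(wi1, "k") <- attr(window_index, "k")
  class(wi1) <- class(window_index)
  res <- scan_introgression(haps, popmap, B = B, seed = seed,
                            recipient = recipient, window_index = wi1)
  list(delta = res$delta[1L], p_emp = res$p_emp[1L], n_ge = res$n_ge[1L])
}

#' Flag candidate introgression windows
#'
#' A window is a candidate when its empirical p-value is below `alpha` and
#' its delta chi-square is positive.
#'
#' @param records scan data.frame from [scan_introgression()] (columns
#'   `p_emp` and `delta`).
#' @param alpha p-value threshold (default 0.001).
#' @return logical vector of per-window flags.
#' @export
call_candidates <- function(records, alpha = 0.001) {
  records$p_emp < alpha & records$delta > 0
}

#' Remove candidates shared with the control population
#'
#' Windows that are also candidates in the control-population scan are
#' removed: signal present in a second ancestral population is attributed
#' to shared ancestry, not donor introgression.  The comparison is
#' window-exact (both scans must use the same `WindowIndex`).
#'
#' @param candidates logical candidate flags for the test population.
#' @param candidates_control logical flags from the control scan.
#' @return filtered logical flags.
#' @export
exclude_control_overlap <- function(candidates, candidates_control) {
  if (length(candidates) != length(candidates_control))
    stop("mismatched WindowIndex: flag vectors differ in length")
  candidates & !candidates_control
}

#' Merge adjacent candidate windows into regions
#'
#' Maximal runs of candidate windows (allowing up to `gap` intervening
#' non-candidate windows) are merged into intervals spanning the first
#' window's start to the last window's end.  Runs never cross chromosome
#' boundaries.
#'
#' @param flags logical per-window candidate flags.
#' @param window_index the matching `WindowIndex`.
#' @param gap maximum number of non-candidate windows bridged (default 0).
#' @return a [RegionSet] with payload columns `window_first`,
#'   `window_last`, `n_windows`.
#' @export
merge_candidate_regions <- function(flags, window_index, gap = 0) {
  if (length(flags) != nrow(window_index))
    stop("flags do not match the window index")
  idx <- which(flags)
  if (!length(idx))
    return(RegionSet(label = "candidate_introgression"))
  ch <- window_index$chrom[idx]
  new_run <- c(TRUE, diff(idx) > gap + 1 | ch[-1] != ch[-length(ch)])
  run_id <- cumsum(new_run)
  first <- idx[!duplicated(run_id)]
  last <- idx[rev(!duplicated(rev(run_id)))]
  RegionSet(window_index$chrom[first],
            window_index$start_bp[first],
            window_index$end_bp[last],
            label = "candidate_introgression",
            window_first = first, window_last = last,
            n_windows = vapply(split(idx, run_id), length, integer(1)))
}

#' Introgressed genome fraction
#'
#' Primary value: percent of windowed bp covered by candidate windows.
#' Also reports the window-count fraction, since region summaries can be
#' denominated either way.
#'
#' @param flags logical per-window candidate flags.
#' @param window_index the matching `WindowIndex`.
#' @return list with `bp_percent` and `window_percent` (both 0..100).
#' @export
introgression_fraction <- function(flags, window_index) {
  if (length(flags) != nrow(window_index))
    stop("flags do not match the window index")
  span <- window_index$end_bp - window_index$start_bp
  list(bp_percent = 100 * sum(span[flags]) / sum(span),
       window_percent = 100 * mean(flags))
}

#' Cross-population sharing of candidate windows
#'
#' For each window in the union of candidates across recipient populations,
#' counts how many populations flag it, and tabulates the histogram of that
#' count with ratios over the union.
#'
#' @param flag_list named list of logical candidate flag vectors, one per
#'   recipient population, all over the same windows.
#' @return data.frame with columns `n_populations`, `n_windows`, `ratio`
#'   (ratios sum to 1 over the observed classes); attribute `per_window`
#'   holds the per-window sharing count.
#' @export
sharing_summary <- function(flag_list) {
  if (length(flag_list) < 2L)
    stop("need candidate flags from at least two populations")
  len <- unique(lengths(flag_list))
  if (length(len) != 1L)
    stop("flag vectors differ in length (different WindowIndex?)")
  counts <- Reduce(`+`, lapply(flag_list, as.integer))
  in_union <- counts > 0L
  tab <- table(counts[in_union])
  out <- data.frame(n_populations = as.integer(names(tab)),
                    n_windows = as.integer(tab),
                    ratio = as.integer(tab) / sum(in_union))
  attr(out, "per_window") <- counts
  out
}
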