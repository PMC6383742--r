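#' Extended haplotype homozygosity decay from a core SNP
#'
#' Starting with all haplotypes in one group at the core, moves site by
#' site away from it; at each site haplotypes identical over the interval
#' from the first flanking site through the current one remain grouped, and
#' `EHH(s) = sum_g choose(c_g, 2) / choose(n, 2)` over group sizes `c_g`.
#' `EHH` is 1 at the core (the core allele itself does not split the
#' groups) and non-increasing outward.  The curve stops early once it
#' reaches 0 (further sites cannot revive it), or below `cutoff` if one is
#' given.
#'
#' @param hapmat 0/1 haplotype matrix (rows = haplotypes) for one
#'   chromosome of one population.
#' @param core core site (column index).
#' @param direction `"right"` (increasing position) or `"left"`.
#' @param cutoff stop extending once EHH drops below this value (the first
#'   sub-cutoff point is still recorded).
#' @return data.frame with columns `site` (column index, starting at the
#'   core) and `ehh`.
#' @export
ehh <- function(hapmat, core, direction = c("right", "left"), cutoff = 0) {
  direction <- match.arg(direction)
  n <- nrow(hapmat)
  if (n < 2L) stop("need at least 2 haplotypes")
  m <- ncol(hapmat)
  sites <- if (direction == "right") {
    if (core < m) seq.int(core + 1L, m) else integer()
  } else {
    if (core > 1L) seq.int(core - 1L, 1L) else integer()
  }
  out_site <- c(core, sites)
  out_ehh <- numeric(length(out_site))
  out_ehh[1L] <- 1
  g <- rep(1L, n)
  denom <- n * (n - 1) / 2
  i <- 1L
  for (s in sites) {
    key <- g * 2L + hapmat[, s]
    g <- match(key, unique(key))
    cnt <- tabulate(g)
    i <- i + 1L
    out_ehh[i] <- sum(cnt * (cnt - 1) / 2) / denom
    if (out_ehh[i] <= 0 || out_ehh[i] < cutoff) break
  }
  data.frame(site = out_site[seq_len(i)], ehh = out_ehh[seq_len(i)])
}

#' Integrated EHH (iHH) for a core SNP
#'
#' Trapezoidal integral of the EHH decay curve over genetic distance, both
#' directions summed.  Physical distance is converted with a flat genetic
#' map (`kb_per_cm`, default 300 kb/cM).  Integration is truncated at the
#' first point where EHH falls below `cutoff` (the partial segment down to
#' that point is included); at a chromosome edge the curve is integrated to
#' the edge.
#'
#' @param curve_left,curve_right EHH curves from [ehh()] (left/right).
#' @param positions bp positions of all sites on the chromosome (indexed by
#'   the curves' `site` column).
#' @param cutoff truncation threshold on EHH (default 0.05).
#' @param kb_per_cm genetic-to-physical conversion.
#' @return iHH in cM x EHH units (0 when the core has no flanking sites).
#' @export
ihh <- function(curve_left, curve_right, positions, cutoff = 0.05,
                kb_per_cm = 300) {
  one_side <- function(curve) {
    if (nrow(curve) < 2L) return(0)
    x <- abs(positions[curve$site] - positions[curve$site[1L]]) /
      (kb_per_cm * 1000)
    e <- curve$ehh
    stop_at <- which(e < cutoff)
    last <- if (length(stop_at)) stop_at[1L] else length(e)
    if (last < 2L) return(0)
    sum(diff(x[seq_len(last)]) *
          (utils::head(e[seq_len(last)], -1) + e[2:last]) / 2)
  }
  one_side(curve_left) + one_side(curve_right)
}

#' Cross-population XP-EHH selection scan
#'
#' For every core SNP, integrates EHH in a reference population A and a
#' test population B, forms `raw = ln(iHH_A / iHH_B)`, standardizes the raw
#' scores genome-wide to z-scores, and takes p-values from the standard
#' normal (two-sided by default; the reported `direction` lets one-sided
#' use downstream).  Positive raw/z indicates longer haplotype
#' homozygosity — ongoing selection — in A; negative, in B.  Windows with
#' at least `min_cores` significant core SNPs (p < `core_alpha`) are called
#' candidate positive-selection regions.
#'
#' @param haps a [HaplotypeSet].
#' @param popmap a [PopulationMap].
#' @param pop_a,pop_b population labels (A = reference, e.g. the ancestor
#'   proxy; B = test population).
#' @param window_index a `WindowIndex` from [build_windows()]; required for
#'   window calls (may be `NULL` to skip them).
#' @param cutoff EHH truncation threshold passed to [ihh()].
#' @param kb_per_cm genetic-to-physical conversion.
#' @param core_alpha per-SNP significance threshold (default 0.05).
#' @param min_cores significant cores required to call a window (default 3).
#' @param one_sided if `TRUE`, p = upper-tail of |z| is replaced by the
#'   one-sided upper tail of z (selection in A).
#' @return list with `records` (per scored core: `site`, `chrom`, `pos`,
#'   `ihh_a`, `ihh_b`, `raw`, `z`, `p`), `calls` (per window:
#'   `n_significant`, `selected`, `direction`), and `n_dropped` (cores with
#'   undefined iHH).
#' @export
xpehh_scan <- function(haps, popmap, pop_a, pop_b, window_index = NULL,
                       cutoff = 0.05, kb_per_cm = 300, core_alpha = 0.05,
                       min_cores = 3, one_sided = FALSE) {
  rows_a <- hap_rows(haps, pop_samples(popmap, pop_a))
  rows_b <- hap_rows(haps, pop_samples(popmap, pop_b))
  if (length(rows_a) < 4L || length(rows_b) < 4L)
    stop("both populations need at least 2 samples")
  recs <- lapply(unique(haps$sites$chrom), function(ch) {
    sel <- which(haps$sites$chrom == ch)
    pos <- haps$sites$pos[sel]
    A <- haps$alleles[rows_a, sel, drop = FALSE]
    B <- haps$alleles[rows_b, sel, drop = FALSE]
    m <- length(sel)
    ia <- ib <- numeric(m)
    for (s in seq_len(m)) {
      ia[s] <- ihh(ehh(A, s, "left", cutoff), ehh(A, s, "right", cutoff),
                   pos, cutoff, kb_per_cm)
      ib[s] <- ihh(ehh(B, s, "left", cutoff), ehh(B, s, "right", cutoff),
                   pos, cutoff, kb_per_cm)
    }
    data.frame(site = sel, chrom = ch, pos = pos, ihh_a = ia, ihh_b = ib)
  })
  recs <- do.call(rbind, recs)
  ok <- recs$ihh_a > 0 & recs$ihh_b > 0
  n_dropped <- sum(!ok)
  if (n_dropped)
    message("dropping ", n_dropped, " core(s) with undefined iHH")
  recs <- recs[ok, , drop = FALSE]
  if (nrow(recs) < 10L) stop("cannot standardize: fewer than 10 scored cores")
  recs$raw <- log(recs$ihh_a / recs$ihh_b)
  recs$z <- (recs$raw - mean(recs$raw)) / stats::sd(recs$raw)
  recs$p <- if (one_sided) stats::pnorm(recs$z, lower.tail = FALSE) else
    2 * stats::pnorm(-abs(recs$z))
  calls <- NULL
  if (!is.null(window_index)) {
    sig <- recs$site[recs$p < core_alpha]
    sigz <- recs$z[recs$p < core_alpha]
    calls <- do.call(rbind, lapply(seq_len(nrow(window_index)), function(w) {
      in_w <- sig >= window_index$first[w] & sig <= window_index$last[w]
      ns <- sum(in_w)
      data.frame(window = window_index$window[w], n_significant = ns,
                 selected = ns >= min_cores,
                 direction = if (ns) sign(sum(sigz[in_w])) else 0)
    }))
  }
  list(records = recs, calls = calls, n_dropped = n_dropped)
}

region_window_flags <- function(x, window_index) {
  if (is.logical(x)) {
    if (length(x) != nrow(window_index))
      stop("flags do not match the window index")
    return(x)
  }
  win_gr <- GenomicRanges::GRanges(
    window_index$chrom,
    IRanges::IRanges(window_index$start_bp + 1, window_index$end_bp))
  if (!nrow(x)) return(rep(FALSE, nrow(window_index)))
  GenomicRanges::countOverlaps(win_gr, as_granges(x)) > 0
}

#' Overlap between introgression and positive-selection calls
#'
#' Window-based summary of how introgressed and selected regions intersect:
#' the introgressed fraction of the whole (windowed) genome and of the
#' selection-called windows, and the selected fraction of the whole genome
#' and of the introgressed windows.
#'
#' @param introgression logical window flags or a [RegionSet].
#' @param selection logical window flags or a [RegionSet].
#' @param window_index the shared `WindowIndex`.
#' @return list of four percentages: `introgressed_of_genome`,
#'   `introgressed_of_selected`, `selected_of_genome`,
#'   `selected_of_introgressed` (conditional values are `NaN` when the
#'   conditioning set is empty).
#' @export
overlap_stats <- function(introgression, selection, window_index) {
  i <- region_window_flags(introgression, window_index)
  s <- region_window_flags(selection, window_index)
  list(introgressed_of_genome = 100 * mean(i),
       introgressed_of_selected = 100 * mean(i[s]),
       selected_of_genome = 100 * mean(s),
       selected_of_introgressed = 100 * mean(s[i]))
}
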