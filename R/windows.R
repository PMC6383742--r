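#' Build non-overlapping k-SNP windows
#'
#' Cuts each chromosome's ordered sites into consecutive windows of exactly
#' `k` SNPs.  A trailing partial window (fewer than `k` sites) is dropped,
#' so each chromosome yields `floor(n_sites / k)` windows and windows never
#' span a chromosome boundary.
#'
#' @param sites site data.frame (columns `chrom`, `pos`) or a [HaplotypeSet].
#' @param k window size in SNPs (2..20).
#' @return A `WindowIndex`: data.frame with columns `window`, `chrom`,
#'   `first`, `last` (site column indices), `start_bp`, `end_bp` (0-based
#'   half-open span from the first to the last site), with attribute `k`.
#' @export
build_windows <- function(sites, k) {
  if (inherits(sites, "HaplotypeSet")) sites <- sites$sites
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("window size k must be at least 2")
  if (k > 20L) stop("window size k must be at most 20")
  chroms <- unique(sites$chrom)
  rows <- lapply(chroms, function(ch) {
    idx <- which(sites$chrom == ch)
    nw <- length(idx) %/% k
    if (!nw) return(NULL)
    first <- idx[seq.int(1L, by = k, length.out = nw)]
    last <- first + k - 1L
    data.frame(chrom = ch, first = first, last = last,
               start_bp = sites$pos[first] - 1L, end_bp = sites$pos[last])
  })
  wi <- do.call(rbind, rows)
  if (is.null(wi))
    wi <- data.frame(chrom = character(), first = integer(),
                     last = integer(), start_bp = integer(),
                     end_bp = integer())
  wi <- cbind(window = seq_len(nrow(wi)), wi)
  rownames(wi) <- NULL
  structure(wi, class = c("WindowIndex", "data.frame"), k = k)
}

hap_strings <- function(haps, wi, w, rows = NULL) {
  cols <- seq.int(wi$first[w], wi$last[w])
  a <- haps$alleles[if (is.null(rows)) TRUE else rows, cols, drop = FALSE]
  apply(a, 1L, paste, collapse = "")
}

window_hap_counts <- function(haps, wi, w, rows = NULL) {
  tab <- table(hap_strings(haps, wi, w, rows))
  stats::setNames(as.integer(tab), names(tab))
}

#' Count distinct haplotypes per population in one window
#'
#' Haplotype identity is the exact k-length allele string: no mismatch
#' tolerance.  Counts within each population sum to twice its sample size.
#'
#' @param haps a [HaplotypeSet].
#' @param window_index a `WindowIndex` from [build_windows()].
#' @param window window number (row of the index).
#' @param popmap a [PopulationMap]; all its populations are tabulated.
#' @return named list: population -> named integer vector of counts
#'   (names are the k-character haplotype strings).
#' @export
count_haplotypes <- function(haps, window_index, window, popmap) {
  pops <- unique(popmap$population)
  out <- lapply(pops, function(p) {
    rows <- hap_rows(haps, pop_samples(popmap, p))
    window_hap_counts(haps, window_index, window, rows)
  })
  stats::setNames(out, pops)
}

#' Long-format haplotype count table over all windows
#'
#' @inheritParams count_haplotypes
#' @return data.frame with columns `window`, `population`, `haplotype`,
#'   `count`.
#' @export
hap_count_table <- function(haps, window_index, popmap) {
  rows <- lapply(seq_len(nrow(window_index)), function(w) {
    cnts <- count_haplotypes(haps, window_index, w, popmap)
    do.call(rbind, lapply(names(cnts), function(p)
      data.frame(window = w, population = p,
                 haplotype = names(cnts[[p]]),
                 count = as.integer(cnts[[p]]))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Compact per-window haplotype codes for the permutation kernel:
# integer matrix (2n x n_windows); codes in 0..(H_w - 1) per window.
encode_windows <- function(haps, wi) {
  a <- haps$alleles
  W <- nrow(wi)
  codes <- matrix(0L, nrow = nrow(a), ncol = W)
  for (w in seq_len(W)) {
    cols <- seq.int(wi$first[w], wi$last[w])
    v <- as.vector(a[, cols, drop = FALSE] %*% 2^(seq_along(cols) - 1))
    codes[, w] <- match(v, sort(unique(v))) - 1L
  }
  codes
}
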