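#' Correlation between introgression density and gene density
#'
#' Cuts the genome into fixed-size bins (1 Mb by default), counts candidate
#' windows and annotated genes per bin — a window or gene is assigned to
#' every bin it overlaps — and reports the Pearson correlation between the
#' two counts with a two-sided p-value from the t-distribution.
#'
#' @param candidates a [RegionSet] of candidate windows/regions, or logical
#'   flags plus `window_index`.
#' @param genes a [RegionSet] of gene intervals (see
#'   [read_gene_annotation()]).
#' @param window_index optional `WindowIndex` when `candidates` is a flag
#'   vector; also defines the binned genome extent.
#' @param bin bin width in bp (default 1e6).
#' @return list with `r`, `p`, `n_bins`, and the per-bin count table
#'   (`bins`).
#' @export
gene_density_correlation <- function(candidates, genes,
                                     window_index = NULL, bin = 1e6) {
  if (is.logical(candidates)) {
    if (is.null(window_index))
      stop("window_index required when candidates are flags")
    candidates <- RegionSet(window_index$chrom[candidates],
                            window_index$start_bp[candidates],
                            window_index$end_bp[candidates],
                            label = "candidates")
  }
  # binned genome: per chromosome, from 0 to the furthest feature end
  ext <- rbind(data.frame(chrom = candidates$chrom, end = candidates$end),
               data.frame(chrom = genes$chrom, end = genes$end))
  if (!is.null(window_index))
    ext <- rbind(ext, data.frame(chrom = window_index$chrom,
                                 end = window_index$end_bp))
  if (!nrow(ext)) stop("no features to bin")
  chr_max <- tapply(ext$end, ext$chrom, max)
  bins <- do.call(rbind, lapply(names(chr_max), function(ch) {
    starts <- seq(0, chr_max[[ch]] - 1, by = bin)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin, chr_max[[ch]]))
  }))
  if (nrow(bins) < 3L) stop("fewer than 3 bins; decrease bin size")
  bin_gr <- GenomicRanges::GRanges(bins$chrom,
                                   IRanges::IRanges(bins$start + 1, bins$end))
  count_in_bins <- function(rs) {
    if (!nrow(rs)) return(integer(nrow(bins)))
    GenomicRanges::countOverlaps(bin_gr, as_granges(rs))
  }
  n_cand <- count_in_bins(candidates)
  n_gene <- count_in_bins(genes)
  if (stats::var(n_gene) == 0 || stats::var(n_cand) == 0)
    stop("zero variance in per-bin counts; correlation undefined")
  ct <- stats::cor.test(n_cand, n_gene, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_bins = nrow(bins),
       bins = cbind(bins, n_candidates = n_cand, n_genes = n_gene))
}
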