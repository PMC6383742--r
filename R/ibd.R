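#' Summarize IBD sharing between population pairs
#'
#' Filters identity-by-descent segments to those with LOD above `lod_min`
#' and length of at least `cm_min` centimorgan (converted to bp with a flat
#' `kb_per_cm` map, 300 kb/cM by default), then sums shared length for
#' every population pair and divides by the product of the two population
#' sizes.  The result is mean shared Mb per individual pair.
#'
#' @param segments data.frame of IBD segments as returned by
#'   [read_ibd_segments()] (columns `sample_a`, `sample_b`, `chrom`,
#'   `start`, `end`, `lod`).
#' @param popmap a [PopulationMap]; every sample in `segments` must appear.
#' @param lod_min keep segments with `lod` strictly greater than this.
#' @param cm_min minimum length in cM.
#' @param kb_per_cm genetic-to-physical conversion (kb per cM).
#' @return data.frame with columns `pop_a`, `pop_b`, `n_segments`,
#'   `total_mb`, `mb_per_pair`.
#' @export
summarize_ibd <- function(segments, popmap, lod_min = 3, cm_min = 1,
                          kb_per_cm = 300) {
  unknown <- setdiff(unique(c(segments$sample_a, segments$sample_b)),
                     popmap$sample)
  if (length(unknown))
    stop("unknown sample(s) in IBD segments: ",
         paste(unknown, collapse = ", "))
  min_bp <- cm_min * kb_per_cm * 1000
  keep <- segments$lod > lod_min & (segments$end - segments$start) >= min_bp
  segments <- segments[keep, , drop = FALSE]
  pop_of <- stats::setNames(popmap$population, popmap$sample)
  pop_sizes <- table(popmap$population)
  pa <- pop_of[segments$sample_a]
  pb <- pop_of[segments$sample_b]
  swap <- pa > pb
  tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
  key <- paste(pa, pb, sep = "\r")
  pieces <- split(seq_len(nrow(segments)), key)
  rows <- lapply(names(pieces), function(k) {
    ix <- pieces[[k]]
    pops <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    total <- sum(segments$end[ix] - segments$start[ix])
    data.frame(pop_a = pops[1L], pop_b = pops[2L], n_segments = length(ix),
               total_mb = total / 1e6,
               mb_per_pair = total / 1e6 /
                 (as.integer(pop_sizes[pops[1L]]) *
                    as.integer(pop_sizes[pops[2L]])))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pop_a = character(), pop_b = character(),
                      n_segments = integer(), total_mb = numeric(),
                      mb_per_pair = numeric())
  rownames(out) <- NULL
  out
}
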