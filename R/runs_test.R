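#' Wald-Wolfowitz runs test for genomic clustering of candidate windows
#'
#' Tests whether candidate and non-candidate windows are randomly ordered
#' along the genome.  A run is a maximal stretch of equal flags; with `n1`
#' candidate and `n2` non-candidate windows the expected number of runs is
#' `R_bar = 2 n1 n2 / (n1 + n2) + 1`, its variance
#' `S_R^2 = 2 n1 n2 (2 n1 n2 - n1 - n2) / ((n1 + n2)^2 (n1 + n2 - 1))`,
#' and `Z = (R - R_bar) / S_R` is compared to the standard normal
#' (|Z| > 1.96 rejects randomness at p < 0.05).  Negative Z means fewer
#' runs than expected, i.e. clustering into introgression "islands".
#'
#' @param flags logical per-window flags ordered by (chrom, position).
#' @param chrom optional chromosome per window; when given, runs never
#'   merge across a chromosome boundary (a boundary always ends a run) and
#'   per-chromosome Z values are reported alongside the genome-wide one.
#' @return list of class `runs_test` with `n1`, `n2`, `R`, `R_bar`, `S_R`,
#'   `Z`, `p` (two-sided normal), and `per_chrom` (data.frame or `NULL`).
#' @export
runs_test <- function(flags, chrom = NULL) {
  flags <- as.logical(flags)
  n1 <- sum(flags); n2 <- sum(!flags)
  if (n1 == 0L || n2 == 0L)
    stop("degenerate sequence: both classes must be present")
  count_runs <- function(x) sum(x[-1] != x[-length(x)]) + 1L
  if (is.null(chrom)) {
    R <- count_runs(flags)
    per_chrom <- NULL
  } else {
    pieces <- split(flags, factor(chrom, levels = unique(chrom)))
    R <- sum(vapply(pieces, count_runs, integer(1)))
    per_chrom <- do.call(rbind, lapply(names(pieces), function(ch) {
      f <- pieces[[ch]]
      if (sum(f) == 0L || sum(!f) == 0L)
        return(data.frame(chrom = ch, n1 = sum(f), n2 = sum(!f),
                          R = count_runs(f), Z = NA_real_))
      z <- runs_test(f)$Z
      data.frame(chrom = ch, n1 = sum(f), n2 = sum(!f),
                 R = count_runs(f), Z = z)
    }))
  }
  n <- n1 + n2
  R_bar <- 2 * n1 * n2 / n + 1
  S2 <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) / (n^2 * (n - 1))
  Z <- (R - R_bar) / sqrt(S2)
  structure(list(n1 = n1, n2 = n2, R = R, R_bar = R_bar, S_R = sqrt(S2),
                 Z = Z, p = 2 * stats::pnorm(-abs(Z)), per_chrom = per_chrom),
            class = "runs_test")
}

#' @export
print.runs_test <- function(x, ...) {
  cat(sprintf("Runs test: n1 = %d, n2 = %d, R = %d (expected %.2f)\n",
              x$n1, x$n2, x$R, x$R_bar))
  cat(sprintf("Z = %.3f, two-sided p = %.3g\n", x$Z, x$p))
  invisible(x)
}
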