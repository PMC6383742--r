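#' Construct a RegionSet
#'
#' A set of genomic intervals in 0-based half-open coordinates (BED
#' convention), optionally carrying per-interval payload columns (window
#' indices, statistic values).  All internal coordinates in the package are
#' 0-based half-open; conversion happens only at the VCF/GFF boundary.
#'
#' @param chrom character vector.
#' @param start,end integer vectors, 0-based half-open (`end > start`).
#' @param label free-text label for the set.
#' @param ... further per-interval payload columns.
#' @return An object of class `RegionSet` (a data.frame with columns
#'   `chrom`, `start`, `end`, plus payload), sorted by (chrom, start).
#' @export
RegionSet <- function(chrom = character(), start = integer(),
                      end = integer(), label = "", ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), ..., stringsAsFactors = FALSE)
  if (nrow(df) && any(df$end <= df$start))
    stop("end <= start at interval(s) ",
         paste(which(df$end <= df$start), collapse = ", "))
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("RegionSet", "data.frame"), label = label)
}

#' @export
print.RegionSet <- function(x, ...) {
  lab <- attr(x, "label")
  cat("RegionSet", if (nzchar(lab)) paste0("'", lab, "'"), ":",
      nrow(x), "interval(s),",
      format(sum(x$end - x$start), big.mark = ","), "bp\n")
  if (nrow(x)) print.data.frame(utils::head(x, 10L))
  invisible(x)
}

as_granges <- function(rs) {
  GenomicRanges::GRanges(rs$chrom,
                         IRanges::IRanges(start = rs$start + 1, end = rs$end))
}

granges_to_regions <- function(gr, label = "") {
  RegionSet(as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
            label = label)
}

#' Merge overlapping or book-ended intervals of a RegionSet
#'
#' @param rs a `RegionSet`.
#' @param gap merge intervals separated by at most `gap` bp (0 merges only
#'   overlapping/adjacent intervals).
#' @return a merged, sorted, non-overlapping `RegionSet`.
#' @export
merge_regions <- function(rs, gap = 0) {
  if (!nrow(rs)) return(rs)
  gr <- GenomicRanges::reduce(as_granges(rs), min.gapwidth = gap + 1)
  granges_to_regions(gr, label = attr(rs, "label"))
}

#' Read a BED file into a RegionSet
#'
#' Accepts BED with 3 or more tab-separated columns, no header.
#'
#' @param path BED file path.
#' @param merge merge overlapping intervals after reading.
#' @param label label for the set (defaults to the file name).
#' @return a `RegionSet`.
#' @export
read_regions <- function(path, merge = FALSE, label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(RegionSet(label = label))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("BED line ", which(nf < 3L)[1L], " has fewer than 3 columns")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric coordinate at BED line ",
         which(is.na(start) | is.na(end))[1L])
  bad <- which(end <= start)
  if (length(bad))
    stop("end <= start at BED line ", bad[1L])
  rs <- RegionSet(chrom, start, end, label = label)
  if (merge) merge_regions(rs) else rs
}

#' Write a RegionSet as BED3
#'
#' Tab-separated, no header; integer coordinates are printed exactly, so
#' `write_regions(read_regions(x))` is bit-exact for sorted disjoint BED3.
#'
#' @param rs a `RegionSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(rs, path) {
  lines <- sprintf("%s\t%s\t%s", rs$chrom,
                   format(rs$start, scientific = FALSE, trim = TRUE),
                   format(rs$end, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene intervals from a GFF3 annotation
#'
#' Keeps features of type `gene` and converts the GFF 1-based inclusive
#' coordinates to the package's 0-based half-open convention.
#'
#' @param path GFF3 file path.
#' @param feature feature type to keep (default `"gene"`).
#' @return a `RegionSet` with one interval per gene.
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 (", path, "): ",
                                          conditionMessage(e)))
  genes <- gr[!is.na(gr$type) & as.character(gr$type) == feature]
  if (!length(genes)) {
    warning("no '", feature, "' features in ", path)
    return(RegionSet(label = "genes"))
  }
  granges_to_regions(genes, label = "genes")
}

#' Read IBD segments (refined-IBD style table)
#'
#' Expects tab-separated columns: sample_a, hap_a, sample_b, hap_b, chrom,
#' start, end, lod — the refined-IBD output dialect.  Coordinates are bp.
#'
#' @param path file path.
#' @return data.frame with columns `sample_a`, `sample_b`, `chrom`, `start`,
#'   `end`, `lod` (one row per segment; empty file gives zero rows).
#' @export
read_ibd_segments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(sample_a = character(), sample_b = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), lod = numeric())
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 8L))
    stop("IBD line ", which(nf != 8L)[1L], " does not have 8 columns")
  f <- function(i) vapply(parts, `[[`, "", i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(f(i)))
    if (anyNA(x)) stop("non-numeric ", what, " at IBD line ",
                       which(is.na(x))[1L])
    x
  }
  seg <- data.frame(sample_a = f(1L), sample_b = f(3L), chrom = f(5L),
                    start = num(6L, "start"), end = num(7L, "end"),
                    lod = num(8L, "lod"), stringsAsFactors = FALSE)
  if (any(seg$end <= seg$start))
    stop("end <= start at IBD line ", which(seg$end <= seg$start)[1L])
  if (any(!is.finite(seg$lod)))
    stop("non-finite LOD at IBD line ", which(!is.finite(seg$lod))[1L])
  seg
}
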