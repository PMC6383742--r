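#' Read phased genotypes from a VCF into a HaplotypeSet
#'
#' Loads a VCF with phased GT fields ("|" separator), keeps biallelic SNP
#' records only, restricts samples to those in the population map, and
#' returns the phased 0/1 allele matrix together with the map.  The scan
#' assumes imputed input: any missing genotype after loading is an error.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param popmap_path path to the population map TSV (columns `sample`,
#'   `population`, `role`), or an existing `PopulationMap`.
#' @param unphased `"error"` (default) to fail on any unphased genotype, or
#'   `"drop"` to drop sites containing one.
#' @param exclude_chroms chromosomes removed before analysis; defaults to
#'   sex and mitochondrial chromosomes, which the scan excludes.
#' @return list with elements `haps` (a [HaplotypeSet]) and `popmap`.
#' @export
read_phased_vcf <- function(path, popmap_path,
                            unphased = c("error", "drop"),
                            exclude_chroms = c("W", "Z", "MT",
                                               "chrW", "chrZ", "chrM")) {
  unphased <- match.arg(unphased)
  popmap <- if (inherits(popmap_path, "PopulationMap")) popmap_path else
    read_popmap(popmap_path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  missing_samples <- setdiff(popmap$sample, colnames(gt))
  if (length(missing_samples))
    stop("samples in popmap absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  gt <- gt[, popmap$sample, drop = FALSE]

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(n_alt))
  alt[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))

  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L
  n_multi <- sum(!keep)
  if (n_multi)
    message("dropping ", n_multi, " non-biallelic-SNP record(s)")
  drop_chr <- chrom %in% exclude_chroms
  if (any(drop_chr & keep))
    message("excluding ", sum(drop_chr & keep), " site(s) on ",
            paste(intersect(unique(chrom), exclude_chroms), collapse = ","))
  keep <- keep & !drop_chr

  idx <- which(keep)
  gt <- gt[idx, , drop = FALSE]
  if (anyNA(gt) || any(gt %in% c(".", "./.", ".|.")))
    stop("unimputed input: missing genotypes present after load")
  has_slash <- grepl("/", gt, fixed = TRUE)
  if (any(has_slash)) {
    if (unphased == "error")
      stop("unphased genotype(s) present (\"/\" separator); ",
           "phase upstream or use unphased = \"drop\"")
    bad_sites <- unique(arrayInd(which(has_slash), dim(gt))[, 1L])
    message("dropping ", length(bad_sites), " site(s) with unphased genotypes")
    ok <- setdiff(seq_len(nrow(gt)), bad_sites)
    gt <- gt[ok, , drop = FALSE]
    idx <- idx[ok]
  }
  if (!nrow(gt)) stop("no usable sites in VCF")

  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  if (!all(c(a1, a2) %in% c("0", "1")))
    stop("GT codes other than 0/1 found; only biallelic phased GT supported")
  n <- ncol(gt); m <- nrow(gt)
  alleles <- matrix(0L, nrow = 2L * n, ncol = m)
  alleles[seq(1L, 2L * n, 2L), ] <- t(matrix(as.integer(a1), m, n))
  alleles[seq(2L, 2L * n, 2L), ] <- t(matrix(as.integer(a2), m, n))

  sites <- data.frame(chrom = chrom[idx], pos = pos[idx],
                      id = names(rr)[idx], ref = ref[idx], alt = alt[idx],
                      stringsAsFactors = FALSE)
  haps <- HaplotypeSet(alleles, sites, colnames(gt))
  list(haps = haps, popmap = popmap)
}

#' Write a HaplotypeSet as a phased VCF
#'
#' Emits a minimal VCF 4.2 with phased GT only.  `read_phased_vcf()` on the
#' result reproduces the allele matrix exactly.
#'
#' @param haps a `HaplotypeSet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(haps, path) {
  n <- n_samples(haps)
  h1 <- haps$alleles[seq(1L, 2L * n, 2L), , drop = FALSE]
  h2 <- haps$alleles[seq(2L, 2L * n, 2L), , drop = FALSE]
  gt <- matrix(paste0(h1, "|", h2), nrow = n)  # samples x sites
  body <- cbind(haps$sites$chrom, haps$sites$pos, haps$sites$id,
                haps$sites$ref, haps$sites$alt, ".", "PASS", ".", "GT",
                t(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", haps$samples), collapse = "\t")),
             con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
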