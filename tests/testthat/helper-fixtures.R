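# Small in-code fixtures shared across test files.

# HaplotypeSet from a character vector of haplotype strings (two consecutive
# strings per sample), sites 1 kb apart on one chromosome.
haps_from_strings <- function(strings, chrom = "1", spacing = 1000) {
  alleles <- do.call(rbind, lapply(strsplit(strings, ""), as.integer))
  n_sites <- ncol(alleles)
  sites <- data.frame(chrom = chrom, pos = spacing * seq_len(n_sites),
                      id = paste0("s", seq_len(n_sites)),
                      ref = "A", alt = "T")
  HaplotypeSet(alleles, sites, paste0("S", seq_len(length(strings) / 2)),
               sort = FALSE)
}

toy_popmap <- function(n_anc, n_rec, n_don, prefix = "S") {
  n <- n_anc + n_rec + n_don
  PopulationMap(paste0(prefix, seq_len(n)),
                rep(c("ANC", "REC", "DON"), times = c(n_anc, n_rec, n_don)),
                c(ANC = "ancestor_proxy", REC = "recipient", DON = "donor"))
}

# random named haplotype-count vectors over a shared alphabet
random_count_pair <- function(H, n_per_pop = 40) {
  keys <- sprintf("h%02d", seq_len(H))
  a <- table(factor(sample(keys, n_per_pop, replace = TRUE), levels = keys))
  b <- table(factor(sample(keys, n_per_pop, replace = TRUE), levels = keys))
  list(a = stats::setNames(as.integer(a), keys),
       b = stats::setNames(as.integer(b), keys))
}

# textbook Pearson chi-square on a 2 x H table (columns with pooled zero
# count removed), via stats::chisq.test
chi2_oracle <- function(countsA, countsB) {
  keys <- union(names(countsA), names(countsB))
  a <- stats::setNames(numeric(length(keys)), keys)
  b <- a
  a[names(countsA)] <- countsA
  b[names(countsB)] <- countsB
  keep <- (a + b) > 0
  tab <- rbind(a[keep], b[keep])
  unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
}

# brute-force ROH oracle: enumerate every maximal valid run by direct
# counting, then select greedily from the left (next run starts after the
# previous one ends), keeping runs that qualify
roh_oracle <- function(genotypes, positions, min_snps = 50,
                       min_length = 5e5, max_het = 1, max_missing = 5) {
  m <- length(genotypes)
  valid <- function(i, j) {
    g <- genotypes[i:j]
    sum(g == 1L, na.rm = TRUE) <= max_het && sum(is.na(g)) <= max_missing
  }
  out <- NULL
  i <- 1L
  while (i <= m) {
    if (!valid(i, i)) { i <- i + 1L; next }
    j <- i
    while (j < m && valid(i, j + 1L)) j <- j + 1L
    g <- genotypes[i:j]
    len <- positions[j] - positions[i] + 1L
    if ((j - i + 1L) >= min_snps || len >= min_length)
      out <- rbind(out, data.frame(start = positions[i], end = positions[j],
                                   n_snps = j - i + 1L,
                                   n_het = sum(g == 1L, na.rm = TRUE),
                                   n_missing = sum(is.na(g))))
    i <- j + 1L
  }
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer())
  out
}

# minimal phased VCF writer for crafting malformed/edge-case inputs
write_toy_vcf <- function(path, samples, rows) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  writeLines(vapply(rows, paste, "", collapse = "\t"), con)
  invisible(path)
}
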