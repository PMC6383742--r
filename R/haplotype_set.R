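#' Construct a HaplotypeSet
#'
#' A `HaplotypeSet` holds a complete, phased 0/1 allele matrix with one row
#' per haplotype (two consecutive rows per sample: rows `2i-1` and `2i`
#' belong to sample `i`) and one column per biallelic site.  Sites are sorted
#' by (chrom, pos); positions are 1-based physical bp.  Missing alleles are
#' not permitted: the class models data after phasing and imputation.
#'
#' @param alleles integer matrix of 0/1 codes, `2 * length(samples)` rows.
#' @param sites data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param samples character vector of sample identifiers.
#' @param sort logical; sort sites by (chrom, pos) (reordering columns).
#' @return An object of class `HaplotypeSet`.
#' @export
HaplotypeSet <- function(alleles, sites, samples, sort = TRUE) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos") %in% names(sites)))
  if (is.null(sites$id))  sites$id  <- paste0(sites$chrom, "_", sites$pos)
  if (is.null(sites$ref)) sites$ref <- "A"
  if (is.null(sites$alt)) sites$alt <- "T"
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (nrow(alleles) != 2L * length(samples))
    stop("allele matrix must have exactly two rows per sample")
  if (ncol(alleles) != nrow(sites))
    stop("allele matrix columns (", ncol(alleles),
         ") do not match site count (", nrow(sites), ")")
  if (anyNA(alleles))
    stop("unimputed input: HaplotypeSet does not allow missing alleles")
  if (!all(alleles %in% c(0L, 1L)))
    stop("allele codes must be 0/1")
  if (sort) {
    ord <- order(sites$chrom, sites$pos)
    if (!identical(ord, seq_len(nrow(sites)))) {
      message("reordering ", sum(ord != seq_len(nrow(sites))),
              " sites into (chrom, pos) order")
      sites <- sites[ord, , drop = FALSE]
      alleles <- alleles[, ord, drop = FALSE]
    }
  }
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(duplicated(p)))
      stop("duplicated positions on chrom ", ch)
  }
  rownames(sites) <- NULL
  structure(list(alleles = alleles, sites = sites,
                 samples = as.character(samples), phased = TRUE),
            class = "HaplotypeSet")
}

#' @export
print.HaplotypeSet <- function(x, ...) {
  cat("HaplotypeSet:", length(x$samples), "samples,",
      nrow(x$sites), "sites on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.HaplotypeSet <- function(x) dim(x$alleles)

#' Number of samples in a HaplotypeSet
#' @param haps a `HaplotypeSet`.
#' @return integer sample count.
#' @export
n_samples <- function(haps) length(haps$samples)

#' Rows of the allele matrix belonging to given samples
#'
#' @param haps a `HaplotypeSet`.
#' @param samples character vector of sample names.
#' @return integer vector of haplotype row indices (two per sample, in order).
#' @export
hap_rows <- function(haps, samples) {
  i <- match(samples, haps$samples)
  if (anyNA(i))
    stop("samples absent from HaplotypeSet: ",
         paste(samples[is.na(i)], collapse = ", "))
  as.integer(rbind(2L * i - 1L, 2L * i))
}

#' Subset a HaplotypeSet by samples and/or sites
#'
#' @param haps a `HaplotypeSet`.
#' @param samples optional character vector of samples to keep.
#' @param sites optional integer vector of site (column) indices to keep.
#' @return a `HaplotypeSet`.
#' @export
subset_haps <- function(haps, samples = NULL, sites = NULL) {
  rows <- if (is.null(samples)) seq_len(nrow(haps$alleles)) else
    hap_rows(haps, samples)
  cols <- if (is.null(sites)) seq_len(ncol(haps$alleles)) else as.integer(sites)
  HaplotypeSet(haps$alleles[rows, cols, drop = FALSE],
               haps$sites[cols, , drop = FALSE],
               if (is.null(samples)) haps$samples else samples,
               sort = FALSE)
}

#' Diploid genotype dosage matrix from a HaplotypeSet
#'
#' @param haps a `HaplotypeSet`.
#' @return integer matrix samples x sites of 0/1/2 alternate-allele dosages.
#' @export
genotype_matrix <- function(haps) {
  n <- n_samples(haps)
  g <- haps$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       haps$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(g) <- haps$samples
  colnames(g) <- haps$sites$id
  g
}

#' Construct a PopulationMap
#'
#' Assigns every analysed sample to exactly one population, and each
#' population to a scan role.  Roles follow the four-population design of the
#' haplotype-similarity scan: `ancestor_proxy` (stand-in for the recipient's
#' wild ancestor), `recipient` (population tested for introgression), `donor`
#' (source of gene flow), `control` (second ancestral population used to
#' subtract shared-ancestry false positives), `outgroup` (D-statistic only)
#' and `other`.
#'
#' @param sample character vector of sample identifiers.
#' @param population character vector, same length, of population labels.
#' @param role named character vector mapping population label -> role, or a
#'   character vector parallel to `sample`.
#' @return An object of class `PopulationMap` (a data.frame with columns
#'   `sample`, `population`, `role`).
#' @export
PopulationMap <- function(sample, population, role) {
  valid <- c("ancestor_proxy", "control", "recipient", "donor",
             "outgroup", "other")
  sample <- as.character(sample); population <- as.character(population)
  if (length(population) != length(sample))
    stop("sample and population must have equal length")
  if (anyDuplicated(sample))
    stop("duplicated sample identifiers: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  if (!is.null(names(role))) {
    miss <- setdiff(unique(population), names(role))
    if (length(miss))
      stop("no role for population(s): ", paste(miss, collapse = ", "))
    role <- unname(role[population])
  }
  role <- as.character(role)
  if (length(role) != length(sample))
    stop("role must be named by population or parallel to sample")
  bad <- setdiff(unique(role), valid)
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(valid, collapse = ", "), ")")
  pr <- unique(data.frame(population, role))
  if (anyDuplicated(pr$population))
    stop("population assigned more than one role")
  structure(data.frame(sample = sample, population = population, role = role,
                       stringsAsFactors = FALSE),
            class = c("PopulationMap", "data.frame"))
}

#' Samples belonging to a population
#' @param popmap a `PopulationMap`.
#' @param population population label.
#' @return character vector of sample names.
#' @export
pop_samples <- function(popmap, population) {
  s <- popmap$sample[popmap$population == population]
  if (!length(s)) stop("population has 0 samples: ", population)
  s
}

#' Population(s) holding a given role
#'
#' @param popmap a `PopulationMap`.
#' @param role one of the scan roles.
#' @param several logical; allow (and return) more than one population.
#' @return character vector of population labels.
#' @export
role_population <- function(popmap, role, several = FALSE) {
  p <- unique(popmap$population[popmap$role == role])
  if (!length(p)) stop("no population with role '", role, "'")
  if (!several && length(p) > 1L)
    stop("more than one population with role '", role, "': ",
         paste(p, collapse = ", "))
  p
}

#' Read a sample-to-population map
#'
#' Expects a tab-separated file with a header line naming at least the
#' columns `sample`, `population` and `role`.
#'
#' @param path file path.
#' @return a `PopulationMap`.
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample", "population", "role")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("popmap is missing column(s): ", paste(miss, collapse = ", "))
  PopulationMap(tab$sample, tab$population, tab$role)
}

#' Write a sample-to-population map
#' @param popmap a `PopulationMap`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(as.data.frame(popmap)[c("sample", "population", "role")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
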