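test_that("phased VCF round-trips through write_phased_vcf/read_phased_vcf", {
  set.seed(42)
  n <- 3; m <- 10
  alleles <- matrix(rbinom(2 * n * m, 1, 0.4), nrow = 2 * n)
  sites <- data.frame(chrom = "1", pos = sort(sample(1e5, m)),
                      id = paste0("rs", 1:m), ref = "A", alt = "C")
  haps <- HaplotypeSet(alleles, sites, c("X1", "X2", "X3"))
  popmap <- PopulationMap(c("X1", "X2", "X3"), c("P", "P", "Q"),
                          c(P = "recipient", Q = "donor"))
  vcf <- tempfile(fileext = ".vcf")
  write_phased_vcf(haps, vcf)
  back <- read_phased_vcf(vcf, popmap)
  expect_equal(back$haps$alleles, haps$alleles)
  expect_equal(back$haps$sites$pos, haps$sites$pos)
  expect_equal(back$haps$samples, haps$samples)
  expect_equal(dim(haps), c(6L, 10L))
})

test_that("unphased and non-biallelic VCF records follow the contract", {
  vcf <- tempfile(fileext = ".vcf")
  write_toy_vcf(vcf, c("A1", "B1"), list(
    c("1", "100", "v1", "A", "C", ".", "PASS", ".", "GT", "0|1", "1|1"),
    c("1", "200", "v2", "A", "C,G", ".", "PASS", ".", "GT", "0|1", "0|2"),
    c("1", "300", "v3", "A", "C", ".", "PASS", ".", "GT", "0/1", "0|0"),
    c("1", "400", "v4", "A", "C", ".", "PASS", ".", "GT", "1|0", "0|0")))
  popmap <- PopulationMap(c("A1", "B1"), c("P", "Q"),
                          c(P = "recipient", Q = "donor"))
  expect_error(suppressMessages(read_phased_vcf(vcf, popmap)), "unphased")
  res <- suppressMessages(read_phased_vcf(vcf, popmap, unphased = "drop"))
  # multi-allelic v2 and unphased v3 gone
  expect_equal(res$haps$sites$pos, c(100L, 400L))

  vcf2 <- tempfile(fileext = ".vcf")
  write_toy_vcf(vcf2, c("A1", "B1"), list(
    c("1", "100", "v1", "A", "C", ".", "PASS", ".", "GT", ".|.", "1|1")))
  expect_error(suppressMessages(read_phased_vcf(vcf2, popmap)),
               "unimputed input")
})

test_that("popmap samples absent from the VCF are reported by name", {
  vcf <- tempfile(fileext = ".vcf")
  write_toy_vcf(vcf, c("A1"), list(
    c("1", "100", "v1", "A", "C", ".", "PASS", ".", "GT", "0|1")))
  popmap <- PopulationMap(c("A1", "GHOST"), c("P", "Q"),
                          c(P = "recipient", Q = "donor"))
  expect_error(read_phased_vcf(vcf, popmap), "GHOST")
})

test_that("sex and mito chromosomes are excluded by default", {
  vcf <- tempfile(fileext = ".vcf")
  write_toy_vcf(vcf, "A1", list(
    c("1", "100", "v1", "A", "C", ".", "PASS", ".", "GT", "0|1"),
    c("Z", "100", "v2", "A", "C", ".", "PASS", ".", "GT", "0|1"),
    c("W", "100", "v3", "A", "C", ".", "PASS", ".", "GT", "1|1"),
    c("MT", "100", "v4", "A", "C", ".", "PASS", ".", "GT", "1|1")))
  popmap <- PopulationMap("A1", "P", c(P = "recipient"))
  res <- suppressMessages(read_phased_vcf(vcf, popmap))
  expect_equal(unique(res$haps$sites$chrom), "1")
})

test_that("BED reading, merging and writing follow the half-open contract", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100"), bed)
  rs <- read_regions(bed)
  expect_equal(nrow(rs), 1L)
  expect_equal(rs$start, 0)
  expect_equal(rs$end, 100)

  writeLines(c("chr1\t0\t100", "chr1\t50\t150", "chr2\t0\t10"), bed)
  merged <- read_regions(bed, merge = TRUE)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$end[merged$chrom == "chr1"], 150)

  # round trip is bit-exact for sorted disjoint input
  lines <- c("chr1\t10\t20", "chr1\t30\t40", "chr2\t5\t9")
  writeLines(lines, bed)
  out <- tempfile(fileext = ".bed")
  write_regions(read_regions(bed), out)
  expect_identical(readLines(out), lines)

  writeLines(c("chr1\t10\t20", "chr1\t50\t50"), bed)
  expect_error(read_regions(bed), "line 2")
  writeLines(c("chr1\t10"), bed)
  expect_error(read_regions(bed), "line 1")
})

test_that("GFF3 gene annotation respects coordinate conventions", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
               "1\tsrc\tgene\t201\t300\t.\t-\t.\tID=g2",
               "2\tsrc\tgene\t51\t150\t.\t+\t.\tID=g3"), gff)
  rs <- read_gene_annotation(gff)
  expect_equal(nrow(rs), 3L)
  g1 <- rs[rs$chrom == "1" & rs$end == 100, ]
  expect_equal(g1$start, 0)           # GFF 1-based inclusive -> 0-based
  expect_equal(sort(unique(rs$chrom)), c("1", "2"))

  writeLines(c("##gff-version 3",
               "1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=t1"), gff)
  expect_warning(rs2 <- read_gene_annotation(gff), "no 'gene' features")
  expect_equal(nrow(rs2), 0L)
})

test_that("IBD segment reader parses the refined-IBD dialect", {
  f <- tempfile()
  writeLines("ind1\t1\tind2\t2\t3\t1000000\t3000000\t4.2", f)
  seg <- read_ibd_segments(f)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$lod, 4.2)
  expect_equal(seg$end - seg$start, 2e6)

  writeLines(character(), f)
  expect_equal(nrow(read_ibd_segments(f)), 0L)

  writeLines("ind1\t1\tind2\t2\t3\t1000000\t3000000", f)
  expect_error(read_ibd_segments(f), "line 1")
  writeLines("ind1\t1\tind2\t2\t3\t1000000\t3000000\tNaNope", f)
  expect_error(read_ibd_segments(f), "lod")
})

test_that("PopulationMap validates roles and assignments", {
  expect_error(PopulationMap("a", "P", c(P = "emperor")), "unknown role")
  expect_error(PopulationMap(c("a", "a"), c("P", "P"), c(P = "donor")),
               "duplicated sample")
  pm <- PopulationMap(c("a", "b", "c"), c("P", "P", "Q"),
                      c(P = "recipient", Q = "donor"))
  expect_equal(pop_samples(pm, "P"), c("a", "b"))
  expect_equal(role_population(pm, "donor"), "Q")
  expect_error(role_population(pm, "control"), "no population")
  f <- tempfile()
  write_popmap(pm, f)
  expect_equal(as.data.frame(read_popmap(f)), as.data.frame(pm))
})

test_that("HaplotypeSet enforces its invariants", {
  a <- matrix(0L, 2, 3)
  s <- data.frame(chrom = "1", pos = c(10L, 20L, 30L))
  expect_s3_class(HaplotypeSet(a, s, "x"), "HaplotypeSet")
  expect_error(HaplotypeSet(a, s, c("x", "y")), "two rows per sample")
  a[1] <- NA
  expect_error(HaplotypeSet(a, s, "x"), "unimputed")
  a[1] <- 2L
  expect_error(HaplotypeSet(a, s, "x"), "0/1")
  s$pos <- c(10L, 10L, 30L)
  expect_error(HaplotypeSet(matrix(0L, 2, 3), s, "x"), "duplicated")
  # out-of-order sites are sorted with a message
  s2 <- data.frame(chrom = "1", pos = c(30L, 10L, 20L))
  expect_message(h <- HaplotypeSet(matrix(rep(c(1L, 0L, 0L), each = 2), 2),
                                   s2, "x"), "reordering")
  expect_equal(h$sites$pos, c(10L, 20L, 30L))
  expect_equal(h$alleles[1, ], c(0L, 0L, 1L))
})
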