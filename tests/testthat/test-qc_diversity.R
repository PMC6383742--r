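test_that("site QC removes low-MAF and low-call-rate sites", {
  # 10 samples x 4 sites: MAF 0.05 boundary behaviour and call rate
  g <- cbind(c(1L, rep(0L, 9)),          # MAF 0.05 -> kept (not < 0.05)
             c(rep(0L, 10)),             # MAF 0    -> removed
             c(rep(1L, 5), rep(0L, 5)),  # MAF 0.25 -> kept
             c(1L, 1L, rep(0L, 8)))
  g2 <- g
  g2[1, 4] <- NA                          # call rate 0.9 < 0.95 -> removed
  res <- qc_filter_sites(g2)
  expect_equal(unname(res$keep), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(res$report["n_fail_maf"]), 1)
  expect_equal(unname(res$report["n_fail_call_rate"]), 1)

  # site with MAF 0.04 removed at the 0.05 threshold
  g3 <- matrix(c(rep(1L, 4), rep(0L, 96)), ncol = 1)  # freq 0.02? 4/200=0.02
  g3[1:8, 1] <- 1L                                    # 8/200 = 0.04
  g3[9:100, 1] <- 0L
  expect_error(qc_filter_sites(g3), "no sites survive QC")

  # 96% call rate with MAF 0.3 retained
  set.seed(8)
  g4 <- matrix(rbinom(100, 2, 0.3), ncol = 2)
  g4[1:2, 1] <- NA  # 48/50 = 0.96
  res4 <- qc_filter_sites(g4)
  expect_true(res4$keep[1])
})

test_that("QC on a HaplotypeSet returns the filtered set", {
  set.seed(1)
  mo <- mosaic_generator(10, 10, 10, n_sites = 50, divergence = 0)
  res <- qc_filter_sites(mo$haps, maf_min = 0.2)
  expect_s3_class(res$haps, "HaplotypeSet")
  expect_equal(ncol(res$haps$alleles), sum(res$keep))
  p <- colMeans(genotype_matrix(res$haps)) / 2
  expect_true(all(pmin(p, 1 - p) >= 0.2))
})

test_that("proportion_polymorphic counts within-population MAF > 0.05", {
  g_mono <- matrix(0L, nrow = 10, ncol = 5)
  expect_equal(proportion_polymorphic(g_mono), 0)
  g_poly <- matrix(rep(c(0L, 2L), each = 5), nrow = 10, ncol = 6)
  expect_equal(proportion_polymorphic(g_poly), 1)
  # 20 sites, 13 polymorphic
  set.seed(7)
  n <- 20
  g <- cbind(matrix(rbinom(n * 13, 2, 0.5), nrow = n),
             matrix(rbinom(n * 7, 2, 0.005) * 0L, nrow = n))
  expect_equal(proportion_polymorphic(g), 13 / 20)
  expect_error(proportion_polymorphic(matrix(integer(), 0, 3)), "empty")
})

test_that("ROH detection handles the canonical cases", {
  pos <- as.integer(seq(1, 1e6, length.out = 60))
  segs <- detect_roh(rep(0L, 60), pos)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start, pos[1])
  expect_equal(segs$end, pos[60])

  het <- rep(c(0L, 1L), 30)
  expect_equal(nrow(detect_roh(het, pos)), 0L)

  expect_error(detect_roh(rep(0L, 3), c(10L, 5L, 20L)), "unsorted")
})

test_that("ROH caller agrees with the brute-force maximal-run oracle", {
  set.seed(11)
  for (rep in 1:50) {
    m <- sample(20:200, 1)
    g <- sample(c(0L, 1L, 2L, NA), m, replace = TRUE,
                prob = c(0.55, 0.1, 0.25, 0.1))
    pos <- as.integer(sort(sample(1e6, m)))
    min_snps <- sample(c(5L, 10L, 50L), 1)
    got <- detect_roh(g, pos, min_snps = min_snps)
    want <- roh_oracle(g, pos, min_snps = min_snps)
    expect_equal(got, want, ignore_attr = TRUE)
    if (nrow(got) > 1L)  # segments never overlap
      expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    # every reported segment satisfies the constraints
    for (i in seq_len(nrow(got))) {
      expect_lte(got$n_het[i], 1)
      expect_lte(got$n_missing[i], 5)
      expect_true(got$n_snps[i] >= min_snps ||
                    (got$end[i] - got$start[i] + 1) >= 5e5)
    }
  }
})

test_that("haplotype diversity identities and formula", {
  expect_equal(haplotype_diversity(c(all_same = 8)), 0)
  expect_equal(haplotype_diversity(rep(1, 8)), 1)
  expect_equal(haplotype_diversity(c(2, 2)), 2 / 3)  # N=4, freqs 0.5/0.5
  expect_error(haplotype_diversity(c(1)), "at least 2")
  # relabeling invariance
  set.seed(3)
  cnt <- c(5, 3, 2, 2)
  expect_equal(haplotype_diversity(cnt), haplotype_diversity(rev(cnt)))
  # redistributing the most frequent haplotype to new distinct ones can
  # only increase H
  h0 <- haplotype_diversity(c(6, 2))
  h1 <- haplotype_diversity(c(5, 2, 1))
  h2 <- haplotype_diversity(c(4, 2, 1, 1))
  expect_true(h0 <= h1 && h1 <= h2)
})

test_that("mean window H saturates with window size", {
  set.seed(21)
  mo <- mosaic_generator(25, 25, 25, n_sites = 600, divergence = 0.2)
  rep <- diversity_report(mo$haps, mo$popmap, window_sizes = c(2, 5, 10, 20),
                          roh_args = list(min_snps = 10))
  h <- as.matrix(rep[, c("H_k2", "H_k5", "H_k10", "H_k20")])
  expect_true(all(h >= 0 & h <= 1))
  # non-decreasing in k up to sampling noise
  expect_true(all(diff(t(h)) > -0.02))
})

test_that("diversity report has per-population rows with bounded Pn", {
  set.seed(4)
  mo <- mosaic_generator(10, 10, 10, n_sites = 100, divergence = 0.3)
  rep <- diversity_report(mo$haps, mo$popmap, window_sizes = 5)
  expect_equal(sort(rep$population), c("ANC", "DON", "REC"))
  expect_true(all(rep$pn >= 0 & rep$pn <= 1))
  expect_true(all(is.finite(rep$H_k5)))
})
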