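test_that("pairwise chi-square identities hold", {
  a <- c(h1 = 10L, h2 = 5L, h3 = 5L)
  expect_equal(pairwise_chi2(a, a), 0)
  # disjoint haplotype sets, 10 vs 10 -> symmetric 2x2-like table, chi2 = 20
  expect_equal(pairwise_chi2(c(x = 10L), c(y = 10L)), 20)
  b <- c(h1 = 3L, h2 = 9L, h4 = 2L)
  expect_equal(pairwise_chi2(a, b), pairwise_chi2(b, a))
  expect_error(pairwise_chi2(c(h1 = 0L), c(h1 = 0L)), "non-empty")
})

test_that("pairwise chi-square matches the textbook contingency oracle", {
  set.seed(101)
  for (i in 1:200) {
    H <- sample(2:12, 1)
    cp <- random_count_pair(H, n_per_pop = sample(c(20, 60, 100), 1))
    expect_equal(pairwise_chi2(cp$a, cp$b), chi2_oracle(cp$a, cp$b),
                 tolerance = 1e-9)
  }
})

test_that("delta chi-square has the introgression sign convention", {
  anc <- c(h1 = 10L, h2 = 10L)
  don <- c(h3 = 15L, h4 = 5L)
  counts <- list(A = anc, R = anc, D = don)
  pm <- PopulationMap(c("a", "r", "d"), c("A", "R", "D"),
                      c(A = "ancestor_proxy", R = "recipient", D = "donor"))
  d1 <- delta_chi2(counts, pm)
  expect_equal(d1$chi2_anc, 0)
  expect_lt(d1$delta, 0)     # recipient identical to the ancestor proxy

  d2 <- delta_chi2(list(A = anc, R = don, D = don), pm)
  expect_equal(d2$chi2_donor, 0)
  expect_gt(d2$delta, 0)     # recipient identical to the donor

  d3 <- delta_chi2(list(A = anc, R = anc, D = anc), pm)
  expect_equal(d3$delta, 0)

  expect_error(delta_chi2(list(A = anc, R = anc), pm), "missing population")

  # swapping ancestor-proxy and donor roles negates delta
  pm_swap <- PopulationMap(c("a", "r", "d"), c("A", "R", "D"),
                           c(A = "donor", R = "recipient",
                             D = "ancestor_proxy"))
  mixed <- list(A = anc, R = c(h1 = 6L, h2 = 6L, h3 = 6L, h4 = 2L), D = don)
  expect_equal(delta_chi2(mixed, pm_swap)$delta, -delta_chi2(mixed, pm)$delta)
})

test_that("scan kernel reproduces the R-level statistics", {
  set.seed(31)
  mo <- mosaic_generator(12, 15, 9, n_sites = 40, divergence = 0.4,
                         donor_fraction = 0.5, tract_sites = 20)
  sc <- scan_introgression(mo$haps, mo$popmap, k = 5, B = 10, seed = 1)
  wi <- attr(sc, "window_index")
  for (w in seq_len(nrow(wi))) {
    cnt <- count_haplotypes(mo$haps, wi, w, mo$popmap)
    expect_equal(sc$chi2_anc[w], pairwise_chi2(cnt$ANC, cnt$REC),
                 tolerance = 1e-12)
    expect_equal(sc$chi2_donor[w], pairwise_chi2(cnt$REC, cnt$DON),
                 tolerance = 1e-12)
    expect_equal(sc$delta[w], sc$chi2_anc[w] - sc$chi2_donor[w])
  }
})

test_that("permutation p-values are lattice-valued, reproducible and sane", {
  set.seed(32)
  mo <- mosaic_generator(10, 10, 10, n_sites = 25, divergence = 0)
  wi <- build_windows(mo$haps$sites, 5)
  r1 <- permutation_test(mo$haps, wi, 2, mo$popmap, B = 200, seed = 9)
  r2 <- permutation_test(mo$haps, wi, 2, mo$popmap, B = 200, seed = 9)
  expect_identical(r1, r2)
  expect_true(r1$p_emp >= 1 / 201 && r1$p_emp <= 1)
  expect_equal(r1$p_emp * 201, round(r1$p_emp * 201))  # (n+1)/(B+1) lattice

  # strong planted signal: observed delta beats all permutations
  mo2 <- mosaic_generator(20, 20, 20, n_sites = 25, divergence = 0.6,
                          donor_fraction = 1, tract_sites = 25)
  wi2 <- build_windows(mo2$haps$sites, 5)
  r3 <- permutation_test(mo2$haps, wi2, 1, mo2$popmap, B = 1000, seed = 2)
  expect_equal(r3$p_emp, 1 / 1001)
  expect_gt(r3$delta, 0)
})

test_that("early stopping preserves candidate flags", {
  set.seed(33)
  mo <- mosaic_generator(25, 25, 25, n_sites = 300, divergence = 0.5,
                         donor_fraction = 0.3)
  full <- scan_introgression(mo$haps, mo$popmap, B = 500, alpha = 0.01,
                             seed = 5)
  fast <- scan_introgression(mo$haps, mo$popmap, B = 500, alpha = 0.01,
                             seed = 5, early_stop = TRUE)
  expect_equal(fast$candidate, full$candidate)
  expect_true(all(fast$b_used <= 500))
})

test_that("candidate calling and control exclusion follow the contracts", {
  rec <- data.frame(p_emp = c(5e-4, 5e-4, 2e-3), delta = c(3.2, -1, 3.2))
  expect_equal(call_candidates(rec), c(TRUE, FALSE, FALSE))

  cand <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  ctrl <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(sum(exclude_control_overlap(cand, ctrl)), 3)
  expect_equal(exclude_control_overlap(cand, rep(FALSE, 6)), cand)
  expect_equal(sum(exclude_control_overlap(cand, cand)), 0)
  expect_error(exclude_control_overlap(cand, ctrl[-1]), "mismatched")
})

test_that("candidate regions merge by adjacency with optional gaps", {
  sites <- data.frame(chrom = rep(c("1", "2"), each = 30),
                      pos = rep(1000L * 1:30, 2))
  wi <- build_windows(sites, 5)   # 6 windows per chromosome
  fl <- rep(FALSE, nrow(wi))
  fl[3:5] <- TRUE
  expect_equal(nrow(merge_candidate_regions(fl, wi)), 1L)

  fl2 <- rep(FALSE, nrow(wi)); fl2[c(3, 5)] <- TRUE
  expect_equal(nrow(merge_candidate_regions(fl2, wi, gap = 0)), 2L)
  expect_equal(nrow(merge_candidate_regions(fl2, wi, gap = 1)), 1L)

  expect_equal(nrow(merge_candidate_regions(rep(FALSE, nrow(wi)), wi)), 0L)

  # runs never cross a chromosome boundary even when windows are adjacent
  fl3 <- rep(FALSE, nrow(wi)); fl3[6:7] <- TRUE   # last of chr1, first of chr2
  expect_equal(nrow(merge_candidate_regions(fl3, wi)), 2L)
})

test_that("introgression fraction is reported in bp and windows", {
  sites <- data.frame(chrom = "1", pos = 1000L * seq_len(500))
  wi <- build_windows(sites, 5)
  fl <- rep(FALSE, 100); fl[1:25] <- TRUE
  fr <- introgression_fraction(fl, wi)
  expect_equal(fr$window_percent, 25)
  expect_equal(fr$bp_percent, 100 * sum((wi$end_bp - wi$start_bp)[fl]) /
                 sum(wi$end_bp - wi$start_bp))
  expect_equal(introgression_fraction(rep(TRUE, 100), wi)$bp_percent, 100)
  expect_equal(introgression_fraction(rep(FALSE, 100), wi)$window_percent, 0)
})

test_that("sharing summary tallies populations per window", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, TRUE, FALSE, FALSE)
  s1 <- sharing_summary(list(p1 = a, p2 = b))
  expect_equal(s1$n_populations, 2L)
  expect_equal(s1$ratio, 1)

  s2 <- sharing_summary(list(p1 = c(TRUE, FALSE), p2 = c(FALSE, TRUE)))
  expect_equal(s2$n_populations, 1L)
  expect_equal(s2$n_windows, 2L)

  set.seed(12)
  fl <- replicate(4, sample(c(TRUE, FALSE), 50, replace = TRUE),
                  simplify = FALSE)
  names(fl) <- paste0("p", 1:4)
  s3 <- sharing_summary(fl)
  counts <- rowSums(do.call(cbind, fl))
  expect_equal(attr(s3, "per_window"), counts, ignore_attr = TRUE)
  for (k in s3$n_populations)
    expect_equal(s3$n_windows[s3$n_populations == k],
                 sum(counts == k))
  expect_equal(sum(s3$ratio), 1)
  expect_error(sharing_summary(list(a)), "at least two")
})
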