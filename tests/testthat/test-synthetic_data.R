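test_that("mosaic truth bookkeeping matches the requested donor fraction", {
  set.seed(61)
  for (frac in c(0.1, 0.2, 0.5)) {
    mo <- mosaic_generator(10, 10, 10, n_sites = 1000, donor_fraction = frac,
                           divergence = 0.3)
    # within one tract granule of the request
    expect_equal(mo$truth$true_donor_fraction, 100 * frac,
                 tolerance = 100 / 1000 + 1e-9)
    expect_equal(nrow(mo$haps$sites), 1000L)
    # per-haplotype tracts never overlap
    tr <- mo$truth$tracts
    for (h in unique(tr$hap)) {
      t_h <- tr[tr$hap == h, ]
      t_h <- t_h[order(t_h$start), ]
      if (nrow(t_h) > 1L)
        expect_true(all(t_h$start[-1] >= t_h$end[-nrow(t_h)]))
    }
  }
})

test_that("mosaic output is deterministic given a seed and exchangeable at F=0", {
  m1 <- mosaic_generator(8, 8, 8, n_sites = 60, donor_fraction = 0.25,
                         divergence = 0.4, seed = 77)
  m2 <- mosaic_generator(8, 8, 8, n_sites = 60, donor_fraction = 0.25,
                         divergence = 0.4, seed = 77)
  expect_identical(m1$haps$alleles, m2$haps$alleles)
  expect_identical(m1$truth$tracts, m2$truth$tracts)
  expect_error(mosaic_generator(5, 5, 5, donor_fraction = 2), "in \\[0, 1\\]")
})

test_that("forward simulation respects migration truth and determinism", {
  cfg <- sim_config(m = 0, rescale_factor = 40, n_sample = 30,
                    init = "sfs")
  s1 <- simulate_forward(cfg, seed = 5)
  expect_equal(s1$truth$true_donor_fraction, 0)
  expect_equal(nrow(s1$truth$tracts), 0L)

  cfg2 <- sim_config(m = 0.005, rescale_factor = 40, n_sample = 30,
                     init = "sfs")
  s2 <- simulate_forward(cfg2, seed = 5)
  s3 <- simulate_forward(cfg2, seed = 5)
  expect_identical(s2$haps$alleles, s3$haps$alleles)
  expect_identical(s2$truth$tracts, s3$truth$tracts)
  expect_gt(s2$truth$true_donor_fraction, 0)

  # roles are wired for the scan
  expect_equal(role_population(s2$popmap, "ancestor_proxy"), "ANC")
  expect_equal(role_population(s2$popmap, "donor"), "DON")
  # haplotype matrix is complete 0/1 with segregating sites only
  f <- colMeans(s2$haps$alleles)
  expect_true(all(f > 0 & f < 1))
})

test_that("rescaling guards and truth fractions behave", {
  expect_error(sim_config(rescale_factor = 200), "over-rescaled")
  # donor fraction grows with migration rate
  set.seed(62)
  fr <- vapply(c(0.002, 0.009), function(m) {
    cfg <- sim_config(m = m, rescale_factor = 40, n_sample = 20,
                      init = "sfs")
    simulate_forward(cfg)$truth$true_donor_fraction
  }, numeric(1))
  expect_true(fr[2] > fr[1])
  expect_equal(unname(fr[2]), 100 * (1 - (1 - 0.009)^200), tolerance = 0.35)
})

test_that("scan evaluation against truth handles edge cases", {
  sites <- data.frame(chrom = "1", pos = 1000L * seq_len(100))
  wi <- build_windows(sites, 5)   # 20 windows of 5 kb
  truth <- structure(list(
    tracts = data.frame(hap = rep(1:4, each = 1), chrom = "1",
                        start = 0, end = 25000),
    true_donor_fraction = 100 * 4 * 25000 / (8 * 1e5),
    n_recipient_haps = 8L, benefit_bp = numeric(),
    genome_length = 1e5), class = "SimTruth")
  # windows 1..5 are donor in half the haplotypes
  perfect <- c(rep(TRUE, 5), rep(FALSE, 15))
  ev <- evaluate_scan(perfect, truth, wi)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$n_true_windows, 5L)

  none <- rep(FALSE, 20)
  ev2 <- evaluate_scan(none, truth, wi)
  expect_equal(ev2$recall, 0)
  expect_true(is.na(ev2$precision))

  # carrier threshold: require more carriers than exist -> no true windows
  ev3 <- evaluate_scan(perfect, truth, wi, hap_fraction = 0.9)
  expect_equal(ev3$n_true_windows, 0L)
  expect_true(is.na(ev3$recall))
})

test_that("toy annotation writes valid GFF3 and respects options", {
  rs <- toy_annotation(25, genome_length = 5e6, seed = 9)
  expect_equal(nrow(rs), 25L)
  expect_true(all(rs$end <= 5e6))
  f <- tempfile(fileext = ".gff3")
  toy_annotation(10, genome_length = 2e6, seed = 3, path = f)
  back <- read_gene_annotation(f)
  fwd <- toy_annotation(10, genome_length = 2e6, seed = 3)
  expect_equal(back$start, fwd$start)
  expect_equal(back$end, fwd$end)
  expect_equal(nrow(toy_annotation(0)), 0L)
  expect_identical(toy_annotation(5, seed = 1)$start,
                   toy_annotation(5, seed = 1)$start)
})

test_that("type-I control: no-migration simulations yield almost no candidates", {
  set.seed(63)
  fr <- vapply(1:3, function(i) {
    cfg <- sim_config(m = 0, rescale_factor = 20, n_sample = 50,
                      init = "sfs")
    sim <- simulate_forward(cfg)
    q <- qc_filter_sites(sim$haps)
    sc <- scan_introgression(q$haps, sim$popmap, k = 5, B = 1000,
                             alpha = 0.001, early_stop = TRUE)
    introgression_fraction(sc$candidate, attr(sc, "window_index"))$bp_percent
  }, numeric(1))
  expect_lte(mean(fr), 1)
})
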