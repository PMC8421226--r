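test_that("chi-square against uniform: perfect fit, extreme skew, scaling", {
  r <- chisq_uniform(c(C = 10, G = 10, T = 10))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$stars, "")
  r2 <- chisq_uniform(c(C = 0, G = 30, T = 0))
  expect_equal(r2$statistic, 60)
  expect_equal(r2$df, 2L)
  expect_true(r2$g_excess)
  expect_equal(r2$stars, "**")
  # uniform profile stays at statistic 0 under scaling
  for (k in c(2, 7, 100)) {
    expect_equal(chisq_uniform(k * c(1, 1, 1))$statistic, 0)
  }
  # category relabeling leaves the statistic unchanged
  expect_equal(chisq_uniform(c(3, 12, 6))$statistic,
               chisq_uniform(c(12, 6, 3))$statistic)
  expect_error(chisq_uniform(c(0, 0, 0)), "no variant counts")
})

test_that("one-sided Fisher matches hand-derived exact values", {
  expect_equal(fisher_one_sided(2, 0, 0, 2)$p_value, 1 / 6)
  expect_equal(fisher_one_sided(0, 5, 5, 0)$p_value, 1)
  expect_gt(fisher_one_sided(5, 5, 5, 5)$p_value, 0.5)
  m <- matrix(c(2, 0, 0, 2), 2, byrow = TRUE)
  expect_equal(fisher_one_sided(m)$p_value, 1 / 6)
})

test_that("Fisher p agrees with enumeration and with fisher.test", {
  set.seed(3)
  for (i in 1:50) {
    t <- sample(0:12, 4, replace = TRUE)
    if (sum(t) == 0) next
    p <- fisher_one_sided(t[1], t[2], t[3], t[4])$p_value
    expect_equal(p, enumerate_fisher_p(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(t, 2, byrow = TRUE),
                             alternative = "greater")$p.value
    expect_equal(p, ft, tolerance = 1e-9)
  }
})

test_that("Fisher p is monotone in the enrichment cell with fixed margins", {
  # margins (10, 10) x (8, 12): a ranges over the support
  for (a in 0:7) {
    p1 <- fisher_one_sided(a, 10 - a, 8 - a, 2 + a)$p_value
    p2 <- fisher_one_sided(a + 1, 9 - a, 7 - a, 3 + a)$p_value
    expect_lte(p2, p1 + 1e-12)
  }
})

test_that("hypergeometric tail: enumeration values, conventions, phyper", {
  expect_equal(hypergeom_tail(4, 2, 2, 2), 1 / 6)
  expect_equal(hypergeom_tail(100, 30, 20, 0), 1)
  expect_equal(hypergeom_tail(100, 30, 20, 21), 0)
  expect_error(hypergeom_tail(10, 20, 5, 1), "inconsistent")
  set.seed(4)
  for (i in 1:30) {
    N <- sample(5:200, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_tail(N, K, n, k),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # log-space summation stays finite and accurate at genome scale
  p <- hypergeom_tail(36899, 15000, 883, 514)
  expect_true(is.finite(p) && p > 0 && p < 1)
  expect_equal(p, stats::phyper(513, 15000, 36899 - 15000, 883,
                                lower.tail = FALSE), tolerance = 1e-9)
})

test_that("hypergeometric pmf sums to one over its support", {
  for (N in c(1, 7, 23, 60)) {
    for (K in unique(pmin(N, c(0, 3, N %/% 2, N)))) {
      for (n in unique(pmin(N, c(0, 1, N %/% 3, N)))) {
        xs <- 0:N
        expect_equal(sum(hypergeom_pmf(N, K, n, xs)), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("spectrum report assembles fractions, both tests and stars", {
  recs <- data.frame(
    chrom = "chr1", start = seq(0, 380, 20), end = seq(13, 393, 20),
    human_seq = "GAACAGAGTGTTC", species = "mm9", status = "ok",
    homolog_seq = c(rep("GAACGGAGTGTTC", 14), rep("GAACCGAGTGTTC", 3),
                    rep("GAACTGAGTGTTC", 3)),
    stringsAsFactors = FALSE)
  occ <- data.frame(chrom = "chr1", start = seq(0, 380, 20),
                    end = seq(13, 393, 20), strand = "+",
                    matched_seq = "GAACAGAGTGTTC", source_genome = "h",
                    stringsAsFactors = FALSE)
  # regulatory track covering exactly the 14 G-variant occurrences
  track <- data.frame(chrom = "chr1", start = seq(0, 260, 20),
                      end = seq(13, 273, 20))
  lab <- classify_regulatory(occ, list(reg = track))
  rep1 <- spectrum_report(classify_homologs(recs), lab)
  expect_equal(rep1$n_variants, 20L)
  expect_equal(rep1$fraction_G, 0.7)
  expect_equal(rep1$regulatory_fraction_G, 1)
  expect_equal(rep1$nonregulatory_fraction_G, 0)
  expect_lt(rep1$fisher_p, 0.05)
  expect_equal(rep1$fisher_stars, "*")
  # empty input: header-only report
  expect_equal(nrow(spectrum_report(recs[0, ])), 0L)
  # a species with zero variants gets NA p-values
  recs2 <- recs[1:2, ]
  recs2$homolog_seq <- "GAACAGAGTGTTC"
  rep2 <- spectrum_report(classify_homologs(recs2), lab)
  expect_true(is.na(rep2$chisq_p) && is.na(rep2$fisher_p))
})
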