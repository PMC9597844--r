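test_that("expected heterozygosity matches hand-computed values", {
  expect_equal(expected_heterozygosity(c(A = 1)), 0)
  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(expected_heterozygosity(c(0.5, 0.3, 0.2)), 0.62)
  expect_error(expected_heterozygosity(numeric(0)), "empty")
  expect_error(expected_heterozygosity(c(0.5, 0.2)), "sum to 1")
})

test_that("unbiased H_E applies the 2N/(2N-1) correction exactly", {
  expect_equal(unbiased_expected_heterozygosity(c(0.5, 0.3, 0.2), 10),
               20 / 19 * 0.62, tolerance = 1e-9)
  expect_equal(unbiased_expected_heterozygosity(c(A = 1), 7), 0)
  # limit: the correction vanishes as N grows
  he <- expected_heterozygosity(c(0.5, 0.5))
  expect_lt(unbiased_expected_heterozygosity(c(0.5, 0.5), 5000) / he, 1 + 1e-3)
  expect_lt(unbiased_expected_heterozygosity(c(0.5, 0.5), 500) / he,
            unbiased_expected_heterozygosity(c(0.5, 0.5), 50) / he)
  expect_error(unbiased_expected_heterozygosity(c(1), 0), "positive")
})

test_that("observed heterozygosity counts non-missing heterozygotes", {
  ds <- toy_two_pop()
  expect_equal(observed_heterozygosity(ds, "L1", "p1"), 0.5)
  # one missing individual is excluded from the denominator
  ds2 <- genotypes(matrix(c(101L, NA), ncol = 1), matrix(c(103L, NA), ncol = 1),
                   c("a", "a"), "L1")
  expect_equal(observed_heterozygosity(ds2, "L1", "a"), 1)
  ds3 <- genotypes(matrix(NA_integer_), matrix(NA_integer_), "a", "L1")
  expect_warning(h <- observed_heterozygosity(ds3, "L1", "a"), "missing")
  expect_true(is.na(h))
})

test_that("effective alleles: equifrequent k gives k, and A_E <= N_A", {
  for (k in 2:6) expect_equal(effective_alleles(rep(1 / k, k)), k)
  expect_equal(effective_alleles(c(0.5, 0.3, 0.2)), 1 / 0.38)
  for (seed in 1:25) {
    p <- with_seed(seed, {x <- stats::rgamma(5, 1); x / sum(x)})
    expect_lte(effective_alleles(p), 5 + 1e-9)
    expect_equal(expected_heterozygosity(p), 1 - 1 / effective_alleles(p),
                 tolerance = 1e-12)
  }
})

test_that("allelic richness matches the hypergeometric closed form", {
  expect_equal(allelic_richness(c(A = 3, B = 1), 2), 1.5)
  # g = N returns the observed allele count
  cnt <- c(a = 4L, b = 7L, c = 1L)
  expect_equal(allelic_richness(cnt, sum(cnt)), 3)
  expect_error(allelic_richness(cnt, 13), "exceeds")
  # monotone non-decreasing in g, and A_R(2) <= 2
  ar <- vapply(2:12, function(g) allelic_richness(cnt, g), numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
  expect_lte(ar[1], 2)
})

test_that("allelic richness agrees with brute-force subsampling", {
  # Monte-Carlo oracle: expected distinct alleles in draws without replacement
  cnt <- c(9L, 5L, 3L, 1L)
  pool <- rep.int(seq_along(cnt), cnt)
  for (g in c(2L, 6L, 12L)) {
    sims <- with_seed(123 + g, {
      vapply(seq_len(20000), function(i) length(unique(sample(pool, g))), numeric(1))
    })
    se <- stats::sd(sims) / sqrt(length(sims))
    expect_lt(abs(mean(sims) - allelic_richness(cnt, g)), 3 * se + 1e-3)
  }
})

test_that("F_IS follows 1 - Ho/He with monomorphic loci undefined", {
  expect_equal(inbreeding_coefficient(0.6, 0.6), 0)
  expect_equal(inbreeding_coefficient(0.6, 0.72), -0.2)
  expect_equal(inbreeding_coefficient(0.5, 0), 1)
  expect_true(is.na(inbreeding_coefficient(0, 0)))
})

test_that("F_IS centers on zero for HWE-sampled populations", {
  base <- small_baseline()
  fis <- vapply(1:200, function(r) {
    ds <- sample_genotypes(base, 30, seed = 5000 + r, pop_names = "p")
    s <- summarize_population(ds, "p", g = 4)
    s$summary$mean[s$summary$metric == "f_is"]
  }, numeric(1))
  expect_gt(mean(fis), -0.05)
  expect_lt(mean(fis), 0.05)
})

test_that("population summaries average over loci with correct SE", {
  # 2-locus fixture engineered to per-locus H_E of 0.5 and 0.62:
  # locus 1 freqs {0.5, 0.5}; locus 2 freqs {0.5, 0.3, 0.2} over 10 copies
  a1 <- cbind(c(101L, 101L, 101L, 103L, 103L), c(101L, 101L, 101L, 103L, 105L))
  a2 <- cbind(c(101L, 101L, 103L, 103L, 103L), c(101L, 101L, 103L, 103L, 105L))
  ds <- genotypes(a1, a2, rep("p", 5), c("L1", "L2"))
  s <- summarize_population(ds, "p", g = 4)
  he <- s$per_locus$exp_het
  expect_equal(he, c(0.5, 0.62))
  row <- s$summary[s$summary$metric == "exp_het", ]
  expect_equal(row$mean, 0.56)
  expect_equal(row$se, stats::sd(he) / sqrt(2), tolerance = 1e-9)
  # all-identical loci give SE = 0 for every metric
  ds2 <- genotypes(cbind(a1[, 1], a1[, 1]), cbind(a2[, 1], a2[, 1]),
                   rep("p", 5), c("L1", "L2"))
  s2 <- summarize_population(ds2, "p", g = 4)
  expect_true(all(s2$summary$se == 0))
})

test_that("diversity_summary has the seven standard metric columns", {
  ds <- random_ds(21, n_pops = 3, n_per_pop = 8, L = 3)
  tab <- diversity_summary(ds)
  metrics <- c("n_alleles", "allelic_richness", "effective_alleles",
               "exp_het", "obs_het", "unbiased_exp_het", "f_is")
  expect_true(all(metrics %in% names(tab)))
  expect_true(all(paste0(metrics, "_se") %in% names(tab)))
  expect_equal(nrow(tab), 3)
  # invariants: A_R <= N_A, A_E <= N_A, uH_E >= H_E
  expect_true(all(tab$allelic_richness <= tab$n_alleles + 1e-9))
  expect_true(all(tab$effective_alleles <= tab$n_alleles + 1e-9))
  expect_true(all(tab$unbiased_exp_het >= tab$exp_het - 1e-12))
})

test_that("uH_E / H_E equals 2N/(2N-1) exactly on complete data", {
  ds <- random_ds(33, n_pops = 2, n_per_pop = 6, L = 2)
  tab <- diversity_summary(ds)
  pl <- attr(tab, "per_locus")
  pl <- pl[pl$exp_het > 0, ]
  expect_equal(pl$unbiased_exp_het / pl$exp_het,
               2 * pl$n / (2 * pl$n - 1), tolerance = 1e-12)
})
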