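test_that("Weir-Cockerham theta reproduces the hand-evaluated toy", {
  th <- wc_theta(toy_two_pop())
  expect_equal(th$theta, 0.515152, tolerance = 1e-6)
  expect_equal(unname(th$components[1, ]),
               c(2 * 0.177083, 2 * -0.020833, 2 * 0.1875), tolerance = 1e-4)
})

test_that("theta is 1 for fixed differences and <= 0 for identical samples", {
  expect_equal(wc_theta(fixed_diff_pop())$theta, 1)
  a1 <- matrix(c(101L, 101L, 103L, 101L, 101L, 103L), ncol = 1)
  a2 <- matrix(c(101L, 103L, 103L, 101L, 103L, 103L), ncol = 1)
  ds <- genotypes(a1, a2, rep(c("p1", "p2"), each = 3), "L1")
  expect_lte(wc_theta(ds)$theta, 0)
  expect_error(wc_theta(subset_populations(ds, "p1")), "two populations")
})

test_that("multilocus theta is the ratio of summed components", {
  # locus 2 differentiates, locus 1 does not: per-locus mean != ratio of sums
  a1 <- cbind(c(101L, 101L, 103L, 101L, 101L, 103L),
              c(101L, 101L, 101L, 109L, 109L, 109L))
  ds <- genotypes(a1, a1, rep(c("p1", "p2"), each = 3), c("L1", "L2"))
  th <- wc_theta(ds)
  comp <- th$components
  expect_equal(th$theta, sum(comp[, "a"]) / sum(comp), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(th$theta, mean(th$per_locus, na.rm = TRUE))))
})

test_that("Hedrick's G'_ST matches hand computation and its defining bounds", {
  res <- hedrick_gprime_st(list(p1 = c(A = 0.75, B = 0.25),
                                p2 = c(A = 0.125, B = 0.875)))
  expect_equal(res$hs, 0.296875, tolerance = 1e-9)
  expect_equal(res$ht, 0.4921875, tolerance = 1e-9)
  expect_equal(res$gst, 0.396825, tolerance = 1e-5)
  expect_equal(res$gprime_st, 0.731922, tolerance = 1e-5)
  # fixed difference -> exactly 1; identical frequencies -> 0
  fixed <- hedrick_gprime_st(list(p1 = c(A = 1), p2 = c(B = 1)))
  expect_equal(fixed$gprime_st, 1)
  same <- hedrick_gprime_st(list(p1 = c(A = 0.6, B = 0.4), p2 = c(A = 0.6, B = 0.4)))
  expect_equal(same$gst, 0)
  expect_equal(same$gprime_st, 0)
  # |G'_ST| >= |G_ST| whenever H_S > 0
  expect_gte(abs(res$gprime_st), abs(res$gst))
  # all monomorphic for the same allele: undefined, flagged
  expect_warning(und <- hedrick_gprime_st(list(p1 = c(A = 1), p2 = c(A = 1))),
                 "undefined")
  expect_true(is.na(und$gprime_st))
})

test_that("dataset-level corrected G'_ST agrees with theta on strong signal", {
  ds <- fixed_diff_pop(n = 8)
  res <- gst_hedrick(ds)
  expect_equal(res$gprime_st, 1, tolerance = 1e-9)
  expect_equal(res$gst, wc_theta(ds)$theta, tolerance = 0.05)
})

test_that("theta and G'_ST are near zero on panmictic splits", {
  base <- small_baseline()
  vals <- vapply(1:200, function(r) {
    ds <- generate_null_metapopulation(base, n_pops = 4, sizes = 10,
                                       seed = 700 + r)
    c(wc_theta(ds)$theta, gst_hedrick(ds)$gprime_st)
  }, numeric(2))
  expect_lt(abs(mean(vals[1, ])), 0.02)
  expect_lt(abs(mean(vals[2, ])), 0.02)
})

test_that("bootstrap CI is degenerate on degenerate data, seeded, and sane", {
  # identical (heterozygous) individuals everywhere -> zero-width interval
  ds <- genotypes(matrix(101L, 6, 1), matrix(103L, 6, 1),
                  rep(c("p1", "p2"), each = 3), "L1")
  ci <- bootstrap_ci(ds, "gprime_st", reps = 100, seed = 1)
  expect_equal(ci$lower, ci$upper)
  # two fixed-difference populations -> CI = [1, 1]
  ci2 <- bootstrap_ci(fixed_diff_pop(), "theta", reps = 100, seed = 1)
  expect_equal(c(ci2$lower, ci2$upper), c(1, 1))
  # seeded reproducibility
  ds3 <- random_ds(5, n_pops = 3, n_per_pop = 6, L = 2)
  c1 <- bootstrap_ci(ds3, "theta", reps = 150, seed = 9)
  c2 <- bootstrap_ci(ds3, "theta", reps = 150, seed = 9)
  expect_identical(c1, c2)
  expect_lte(c1$lower, c1$upper)
  expect_error(bootstrap_ci(ds3, "theta", reps = 50), ">= 100")
})

test_that("null-split bootstrap CIs for global theta usually span zero", {
  # panmictic pool split into 14 pseudo-populations of 10: the 95% CI should
  # contain zero in >= 90% of seeded runs (checked on 60 runs, 2-SE slack)
  base <- generate_baseline(seed = 42)
  hits <- vapply(1:60, function(r) {
    ds <- generate_null_metapopulation(base, n_pops = 14, sizes = 10,
                                       seed = 900 + r)
    ci <- bootstrap_ci(ds, "theta", reps = 250, seed = r)
    ci$lower <= 0 && ci$upper >= 0
  }, logical(1))
  expect_gte(mean(hits), 0.9 - 2 * sqrt(0.9 * 0.1 / 60))
})

# exact enumeration of 2-column tables with fixed margins (oracle)
enumerate_exact_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  lp_obs <- msatpower:::log_table_prob(tab)
  cells <- expand.grid(lapply(rs, function(r) 0:min(r, cs[1])))
  p_tot <- 0; p_le <- 0
  for (i in seq_len(nrow(cells))) {
    c1 <- as.numeric(cells[i, ])
    if (sum(c1) != cs[1]) next
    t2 <- cbind(c1, rs - c1)
    lp <- msatpower:::log_table_prob(t2)
    pr <- exp(lp)
    p_tot <- p_tot + pr
    if (lp <= lp_obs + 1e-9) p_le <- p_le + pr
  }
  p_le / p_tot
}

test_that("Monte-Carlo exact test converges to the enumeration p-value", {
  tabs <- list(
    matrix(c(6L, 2L, 2L, 6L), 2, byrow = TRUE),
    matrix(c(5L, 1L, 3L, 3L, 0L, 4L), 3, byrow = TRUE),
    matrix(c(2L, 2L, 4L, 0L, 1L, 3L), 3, byrow = TRUE)
  )
  for (tab in tabs) {
    p_exact <- enumerate_exact_p(tab)
    reps <- 20000L
    p_mc <- exact_genic_test(tab, mc_reps = reps, seed = 77)
    se <- sqrt(p_exact * (1 - p_exact) / reps)
    expect_lt(abs(p_mc - p_exact), 3 * se + 2 / reps)
  }
})

test_that("exact test boundary behavior: identical vs disjoint populations", {
  same <- matrix(c(5L, 5L, 5L, 5L), 2)
  expect_gte(exact_genic_test(same, mc_reps = 2000, seed = 1), 0.5)
  disjoint <- matrix(c(20L, 0L, 0L, 20L), 2)
  expect_lte(exact_genic_test(disjoint, mc_reps = 5000, seed = 1), 0.001)
  expect_error(exact_genic_test(matrix(0L, 2, 2)), "empty")
})

test_that("Fisher combination floors p-values and matches closed forms", {
  r <- fisher_combine(c(1, 1, 1))
  expect_equal(r$chisq, 0)
  expect_equal(r$p, 1)
  r2 <- fisher_combine(c(0.05, 0.5))
  expect_equal(r2$chisq, 7.37776, tolerance = 1e-5)
  expect_equal(r2$df, 4)
  expect_equal(r2$p, 0.1172, tolerance = 1e-3)
  # an extreme locus is treated as exactly 1e-4
  r3 <- fisher_combine(c(1e-8, 0.5))
  expect_equal(r3$chisq, -2 * (log(1e-4) + log(0.5)), tolerance = 1e-9)
  expect_error(fisher_combine(numeric(0)), "no p-values")
  expect_error(fisher_combine(c(0, 0.5)), "in \\(0, 1\\]")
})

test_that("Narum adjustment divides by the harmonic number", {
  expect_equal(narum_adjust(0.05, 1), 0.05)
  expect_equal(narum_adjust(0.05, 91), 0.009816, tolerance = 1e-4)
  k <- 1:30
  a <- vapply(k, function(kk) narum_adjust(0.05, kk), numeric(1))
  expect_true(all(diff(a) < 0))
  expect_error(narum_adjust(0.05, 0), ">= 1")
})

test_that("pairwise matrices carry theta below and G'_ST above the diagonal", {
  ds <- random_ds(13, n_pops = 3, n_per_pop = 8, L = 3)
  pw <- pairwise_differentiation(ds, method = "chisq", seed = 4)
  m <- pw$matrix
  expect_equal(m["pop2", "pop1"], wc_theta(ds, c("pop1", "pop2"))$theta)
  expect_equal(m["pop1", "pop2"], gst_hedrick(ds, c("pop1", "pop2"))$gprime_st)
  expect_equal(pw$alpha_adj, narum_adjust(0.05, 3))
  expect_true(all(is.na(diag(m))))
})
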