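# shared fixtures, built in code

with_seed <- msatpower:::with_seed

# two-population toy with a hand-checkable theta:
# pop1 = {AA, AA, AB, AB}, pop2 = {AB, BB, BB, BB}; A = 101, B = 103
toy_two_pop <- function() {
  genotypes(
    a1 = matrix(c(101, 101, 101, 101, 101, 103, 103, 103), ncol = 1),
    a2 = matrix(c(101, 101, 103, 103, 103, 103, 103, 103), ncol = 1),
    pop = rep(c("p1", "p2"), each = 4), loci = "L1"
  )
}

# two populations fixed for different alleles
fixed_diff_pop <- function(n = 5L, L = 2L) {
  a <- rbind(matrix(101L, n, L), matrix(109L, n, L))
  genotypes(a, a, rep(c("p1", "p2"), each = n), paste0("L", seq_len(L)))
}

# random multi-population dataset for round-trip / property checks
random_ds <- function(seed, n_pops = 3L, n_per_pop = 4L, L = 2L,
                      digits = 3L, missing_rate = 0) {
  with_seed(seed, {
    n <- n_pops * n_per_pop
    sizes <- sample.int(10^digits - 1L, 4L)
    a1 <- matrix(sample(sizes, n * L, replace = TRUE), n, L)
    a2 <- matrix(sample(sizes, n * L, replace = TRUE), n, L)
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(n * L) < missing_rate, n, L)
      a1[drop] <- NA_integer_
      a2[drop] <- NA_integer_
    }
    genotypes(a1, a2, rep(paste0("pop", seq_len(n_pops)), each = n_per_pop),
              paste0("L", seq_len(L)))
  })
}

# sorted allele-count multiset per locus x population, for round-trip equality
allele_multiset <- function(ds) {
  lapply(ds$loci, function(loc)
    lapply(levels(ds$pop), function(p) allele_counts(ds, loc, p)))
}

small_baseline <- function(seed = 42) {
  generate_baseline(synthetic_spec(L = 4L, total_alleles = 30L), seed = seed)
}
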