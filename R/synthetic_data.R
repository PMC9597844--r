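#' Specification for the synthetic microsatellite baseline
#'
#' Describes the marker panel and sampling design the generator emulates: a
#' small battery of dinucleotide (plus one tetranucleotide) microsatellite
#' loci typed on a set of small population samples, with 84 alleles over 8
#' loci, 14 populations of 8-16 individuals (mean about 9.4) and mean
#' expected heterozygosity around 0.62 (per-population range roughly
#' 0.55-0.70) — the structure of the empirical limpet panel this package
#' was designed around.
#'
#' @param L Number of loci.
#' @param total_alleles Total allele count across loci.
#' @param n_pops Number of populations.
#' @param size_range Admissible per-population sample sizes.
#' @param target_he Target mean expected heterozygosity.
#' @param motif Per-locus repeat motif length in bp (recycled to `L`).
#' @param min_size Per-locus minimum allele size in bp (recycled to `L`).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(L = 8L, total_alleles = 84L, n_pops = 14L,
                           size_range = 8:16, target_he = 0.62,
                           motif = c(2L, 2L, 2L, 2L, 4L, 2L, 2L, 2L),
                           min_size = c(123L, 188L, 386L, 143L, 312L, 225L, 90L, 124L)) {
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  if (total_alleles < 2L * L) stop("infeasible: need at least 2 alleles per locus")
  structure(list(L = L, total_alleles = as.integer(total_alleles),
                 n_pops = as.integer(n_pops), size_range = as.integer(size_range),
                 target_he = target_he,
                 motif = rep_len(as.integer(motif), L),
                 min_size = rep_len(as.integer(min_size), L)),
            class = "synthetic_spec")
}

# random composition of `total` into `L` parts, each within [lo, hi]
draw_allele_counts <- function(total, L, lo, hi) {
  if (total < L * lo || total > L * hi) stop("infeasible allele-count composition")
  repeat {
    k <- lo + as.vector(stats::rmultinom(1L, total - L * lo,
                                         rep(1 / L, L)))
    if (all(k <= hi)) return(k)
  }
}

# temper a raw weight vector w to hit a target gene diversity:
# p(beta) ~ w^beta, He(beta) strictly decreasing in beta
temper_to_he <- function(w, target) {
  he_of <- function(beta) {
    p <- w^beta
    p <- p / sum(p)
    1 - sum(p^2)
  }
  k <- length(w)
  if (target >= 1 - 1 / k) target <- 1 - 1 / k - 1e-6
  lo <- 0; hi <- 1
  while (he_of(hi) > target) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (he_of(mid) > target) lo <- mid else hi <- mid
  }
  p <- w^((lo + hi) / 2)
  p / sum(p)
}

#' Generate a synthetic baseline allele-frequency pool
#'
#' Draws a single ancestral pool of allele frequencies matching a
#' [synthetic_spec()]: allele counts per locus sum to the specified total
#' (each locus keeps at least 5 alleles so all loci are usefully
#' polymorphic); allele sizes are `min_size + motif * (0:(k-1))`; raw
#' frequency weights come from a symmetric Dirichlet and are then tempered
#' (powered and renormalized, a monotone bisection) so each locus hits its
#' gene-diversity target; the per-locus targets are spread around
#' `target_he` and kept inside [0.4, 0.8]. Deterministic under `seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed.
#' @return List of per-locus named frequency vectors (names = allele sizes
#'   in bp) with attributes `motif` and `repeat_bounds`; class `baseline`.
#' @export
generate_baseline <- function(spec = synthetic_spec(), seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    lo <- max(2L, min(5L, spec$total_alleles %/% spec$L - 1L))
    hi <- min(30L, spec$total_alleles - (spec$L - 1L) * lo)
    k <- draw_allele_counts(spec$total_alleles, spec$L, lo, hi)
    targets <- stats::runif(spec$L, spec$target_he - 0.07, spec$target_he + 0.07)
    targets <- targets + (spec$target_he - mean(targets))
    targets <- pmin(pmax(targets, 0.40), pmin(0.80, 1 - 1 / k - 1e-6))
    baseline <- vector("list", spec$L)
    names(baseline) <- paste0("loc", seq_len(spec$L))
    for (j in seq_len(spec$L)) {
      w <- stats::rgamma(k[j], shape = 1)
      p <- temper_to_he(w, targets[j])
      sizes <- spec$min_size[j] + spec$motif[j] * (seq_len(k[j]) - 1L)
      baseline[[j]] <- stats::setNames(p, sizes)
    }
    attr(baseline, "motif") <- spec$motif
    attr(baseline, "target_he") <- spec$target_he
    class(baseline) <- c("baseline", "list")
    baseline
  })
}

#' @export
print.baseline <- function(x, ...) {
  k <- vapply(x, length, integer(1))
  he <- vapply(x, function(p) 1 - sum(p^2), numeric(1))
  cat("Synthetic baseline:", length(x), "loci,", sum(k), "alleles, mean H_E =",
      round(mean(he), 3), "\n")
  print(data.frame(locus = names(x), alleles = k, He = round(he, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Draw per-population sample sizes emulating a small-sample survey
#'
#' Right-skewed sizes on `8..16` with mean close to 9.4 (most sites near the
#' minimum, a few larger), drawn from a truncated-geometric weight on the
#' offset above the minimum.
#'
#' @param n_pops Number of populations.
#' @param seed Optional integer seed.
#' @return Integer vector of sample sizes.
#' @export
draw_sample_sizes <- function(n_pops = 14L, seed = NULL) {
  with_seed(seed, {
    offs <- 0:8
    w <- 0.58^offs
    8L + sample(offs, n_pops, replace = TRUE, prob = w / sum(w))
  })
}

#' Generate a null metapopulation (zero true differentiation)
#'
#' Samples every population independently from the same baseline pool under
#' Hardy-Weinberg proportions, so true differentiation is exactly zero —
#' the reference construction for alpha-error calibration and
#' CI-spans-zero checks.
#'
#' @param baseline Baseline from [generate_baseline()].
#' @param n_pops Number of populations.
#' @param sizes Per-population diploid sample sizes (scalar, vector, or
#'   `NULL` to draw them with [draw_sample_sizes()]).
#' @param seed Optional integer seed.
#' @return A [genotypes] object.
#' @export
generate_null_metapopulation <- function(baseline, n_pops = 14L, sizes = NULL,
                                         seed = NULL) {
  with_seed(seed, {
    sizes <- sizes %||% draw_sample_sizes(n_pops)
    sizes <- rep_len(as.integer(sizes), n_pops)
    if (any(sizes < 1L)) stop("sizes must be positive")
    pops <- rep(list(lapply(baseline, identity)), n_pops)
    sample_genotypes(pops, sizes)
  })
}

#' Generate an unbottlenecked / bottlenecked population pair
#'
#' One replicate each of a large constant-size population and a ten-fold
#' bottlenecked one after `years` years of the forward simulator, exported
#' as genotype snapshots for subsampling experiments.
#'
#' @param spec A [synthetic_spec()] for the shared baseline.
#' @param Ne_large Size of the unbottlenecked population (default 500).
#' @param Ne_small Post-bottleneck size (default 50).
#' @param years Simulated years (default 100).
#' @param seed Optional integer seed.
#' @param cfg A [life_cycle()] configuration.
#' @return List with [genotypes] objects `large` and `small`, plus the
#'   shared `baseline`.
#' @export
generate_bottlenecked_pair <- function(spec = synthetic_spec(), Ne_large = 500L,
                                       Ne_small = 50L, years = 100L, seed = NULL,
                                       cfg = life_cycle()) {
  base <- generate_baseline(spec, seed = if (is.null(seed)) NULL else derive_seed(seed, 1L))
  big <- run_scenario(base, N0 = Ne_large, N_post = Ne_large, years = years,
                      replicates = 1L, cfg = cfg,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, 2L),
                      snapshot_years = years)
  small <- run_scenario(base, N0 = Ne_large, N_post = Ne_small, years = years,
                        replicates = 1L, cfg = cfg,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, 3L),
                        snapshot_years = years)
  list(large = big$snapshots[[as.character(years)]][[1L]],
       small = small$snapshots[[as.character(years)]][[1L]],
       baseline = base)
}
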