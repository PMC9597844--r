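#' Expected F_ST after t generations of pure drift
#'
#' Closed form for populations of constant effective size `Ne` diverging by
#' drift alone from a common ancestral pool:
#' \eqn{F_{ST}(t) = 1 - (1 - \frac{1}{2N_e})^t}.
#'
#' @param Ne Effective population size (>= 1).
#' @param t Generations since divergence (>= 0).
#' @return Expected F_ST in `[0, 1)`.
#' @examples
#' expected_fst(1000, 20) # 0.009953
#' @export
expected_fst <- function(Ne, t) {
  if (any(Ne < 1)) stop("Ne must be >= 1")
  if (any(t < 0)) stop("t must be >= 0")
  1 - (1 - 1 / (2 * Ne))^t
}

#' Drift duration matching a target divergence level
#'
#' Inverts [expected_fst()]: the integer number of generations at which the
#' drift expectation is closest to `level`.
#'
#' @param Ne Effective population size.
#' @param level Target divergence level (expected F_ST).
#' @return Integer number of generations.
#' @export
generations_for_fst <- function(Ne, level) {
  if (level < 0 || level >= 1) stop("level must lie in [0, 1)")
  if (level == 0) return(0L)
  as.integer(round(log(1 - level) / log(1 - 1 / (2 * Ne))))
}

#' Drift a baseline into independently diverged populations
#'
#' Each population starts from the same baseline allele frequencies and
#' drifts independently for `t` generations, each generation a multinomial
#' resampling of `2 Ne` gene copies per locus. `t = 0` returns the baseline
#' unchanged for every population. Allele frequencies are a martingale under
#' this process, so the expected frequency of every allele equals its
#' baseline value at any `t`.
#'
#' @param baseline List of per-locus named allele-frequency vectors
#'   (names are allele codes), e.g. from [generate_baseline()].
#' @param n_pops Number of populations to diverge.
#' @param Ne Effective population size per population.
#' @param t Generations since divergence.
#' @param seed Optional integer seed.
#' @return List of length `n_pops`; each element a per-locus list of named
#'   frequency vectors (alleles with zero frequency dropped).
#' @export
drift_populations <- function(baseline, n_pops, Ne, t, seed = NULL) {
  stopifnot(is.list(baseline), length(baseline) > 0L)
  if (t == 0L) {
    return(rep(list(lapply(baseline, function(p) p[p > 0])), n_pops))
  }
  two_ne <- as.integer(2 * Ne)
  with_seed(seed, {
    lapply(seq_len(n_pops), function(i) {
      lapply(baseline, function(p) {
        cnt <- as.vector(stats::rmultinom(1L, two_ne, p))
        if (t > 1L) for (gen in 2:t) {
          cnt <- as.vector(stats::rmultinom(1L, two_ne, cnt))
        }
        q <- cnt / two_ne
        names(q) <- names(p)
        q[q > 0]
      })
    })
  })
}

#' Sample diploid genotypes from per-population allele frequencies
#'
#' Draws `2S` gene copies per locus under Hardy-Weinberg proportions and
#' pairs them into `S` diploid individuals per population.
#'
#' @param pop_freqs Either a per-locus frequency list (one population) or a
#'   list of such lists (several populations, e.g. from
#'   [drift_populations()]).
#' @param S Diploid sample size per population (scalar or one per
#'   population).
#' @param seed Optional integer seed.
#' @param pop_names Optional population labels.
#' @return A [genotypes] object.
#' @export
sample_genotypes <- function(pop_freqs, S, seed = NULL, pop_names = NULL) {
  single <- !is.list(pop_freqs[[1L]])
  if (single) pop_freqs <- list(pop_freqs)
  n_pops <- length(pop_freqs)
  S <- rep_len(as.integer(S), n_pops)
  if (any(S < 1L)) stop("S must be >= 1")
  loci <- names(pop_freqs[[1L]]) %||% paste0("loc", seq_along(pop_freqs[[1L]]))
  pop_names <- pop_names %||% sprintf("pop_%02d", seq_len(n_pops))
  with_seed(seed, {
    a1 <- a2 <- matrix(NA_integer_, sum(S), length(loci))
    offset <- 0L
    for (i in seq_len(n_pops)) {
      rows <- offset + seq_len(S[i])
      for (j in seq_along(loci)) {
        p <- pop_freqs[[i]][[j]]
        sizes <- as.integer(names(p))
        draw <- sizes[sample.int(length(p), 2L * S[i], replace = TRUE, prob = p)]
        a1[rows, j] <- draw[seq_len(S[i])]
        a2[rows, j] <- draw[S[i] + seq_len(S[i])]
      }
      offset <- offset + S[i]
    }
    genotypes(a1, a2, factor(rep(pop_names, S), levels = pop_names), loci)
  })
}

#' Symmetric finite-island model simulator
#'
#' Forward Wright-Fisher simulation of `n_demes` demes of `Ne` diploids
#' exchanging migrants symmetrically: each gene copy immigrates with
#' probability `m` from a uniformly chosen other deme. Loci follow a strict
#' stepwise mutation model (rate `mu` per gene copy per generation, +/- one
#' repeat unit, reflecting at repeat counts `bounds[1]` and `bounds[2]`).
#' After `burn_in` generations `S` diploids are sampled (gene copies without
#' replacement) from each deme. Allele codes in the output are sizes in bp:
#' `repeat_count * motif + offset`.
#'
#' @param n_demes Number of demes (default 10).
#' @param Ne Diploid effective size per deme.
#' @param m Migration rate per gene copy per generation.
#' @param S Diploid sample size per deme.
#' @param L Number of loci (default 8).
#' @param mu Stepwise mutation rate (default 5e-4).
#' @param burn_in Generations to simulate before sampling; default
#'   `10 * Ne`, by which F_ST has long passed its equilibrium time scale
#'   `~1/(1/(2 Ne) + 2 m)` generations for the parameter grids of interest.
#' @param n_init_alleles Number of equifrequent repeat classes every deme
#'   starts with (default 10, centred in the allowed repeat range).
#' @param bounds Reflecting bounds on the repeat count (default `c(5, 60)`).
#' @param motif Repeat motif length in bp used to encode output allele sizes.
#' @param seed Optional integer seed.
#' @param monitor Record the among-deme F_ST trend during burn-in (every
#'   `max(Ne, 50)` generations); if the last two monitoring windows differ
#'   by more than 10% a non-convergence warning is attached to the result
#'   (attribute `converged`).
#' @return A [genotypes] object (`n_demes` populations of `S` individuals)
#'   with attributes `fst_trace` (monitored values) and `converged`.
#' @export
island_model_sim <- function(n_demes = 10L, Ne = 100L, m = 0.01, S = 30L,
                             L = 8L, mu = 5e-4, burn_in = NULL,
                             n_init_alleles = 10L, bounds = c(5L, 60L),
                             motif = 2L, seed = NULL, monitor = TRUE) {
  if (m < 0 || m > 1) stop("m must lie in [0, 1]")
  if (mu < 0) stop("mu must be >= 0")
  if (S > Ne) stop("cannot sample S = ", S, " diploids from demes of Ne = ", Ne)
  burn_in <- as.integer(burn_in %||% (10L * Ne))
  states <- bounds[1L]:bounds[2L]
  K <- length(states)
  two_ne <- 2L * Ne
  init_states <- seq(floor((K - n_init_alleles) / 2) + 1L, length.out = n_init_alleles)
  check_every <- max(as.integer(Ne), 50L)
  with_seed(seed, {
    # counts[k, deme] per locus: gene-copy counts over repeat classes
    cnts <- rep(list(matrix(0L, K, n_demes)), L)
    for (j in seq_len(L)) {
      base <- as.vector(stats::rmultinom(1L, two_ne,
                                         rep(1 / n_init_alleles, n_init_alleles)))
      cnts[[j]][init_states, ] <- base
    }
    trace <- numeric(0)
    for (gen in seq_len(burn_in)) {
      for (j in seq_len(L)) {
        P <- cnts[[j]] / two_ne
        if (n_demes > 1L && m > 0) {
          others <- (rowSums(P) %o% rep(1, n_demes) - P) / (n_demes - 1L)
          P <- (1 - m) * P + m * others
        }
        nxt <- vapply(seq_len(n_demes), function(d)
          as.vector(stats::rmultinom(1L, two_ne, P[, d])), integer(K))
        if (mu > 0) nxt <- apply_stepwise_mutation(nxt, mu, K)
        cnts[[j]] <- nxt
      }
      if (monitor && gen %% check_every == 0L) {
        trace <- c(trace, fst_from_counts(cnts, two_ne))
      }
    }
    converged <- TRUE
    if (monitor && length(trace) >= 2L) {
      a <- trace[length(trace) - 1L]; b <- trace[length(trace)]
      if (is.finite(a) && is.finite(b) && a > 0 && abs(b - a) / a > 0.10) {
        converged <- FALSE
        warning("island-model burn-in may not have converged: F_ST still trending (",
                signif(a, 3), " -> ", signif(b, 3), ")")
      }
    }
    # sample S diploids per deme without replacement from the gene pool
    a1 <- a2 <- matrix(NA_integer_, n_demes * S, L)
    for (d in seq_len(n_demes)) {
      rows <- (d - 1L) * S + seq_len(S)
      for (j in seq_len(L)) {
        pool <- rep.int(states, cnts[[j]][, d])
        draw <- sample(pool, 2L * S)
        a1[rows, j] <- draw[seq_len(S)] * motif + 100L
        a2[rows, j] <- draw[S + seq_len(S)] * motif + 100L
      }
    }
    ds <- genotypes(a1, a2,
                    factor(rep(sprintf("deme_%02d", seq_len(n_demes)), each = S)),
                    paste0("loc", seq_len(L)))
    attr(ds, "fst_trace") <- trace
    attr(ds, "converged") <- converged
    ds
  })
}

# stepwise +/-1 mutation with reflecting bounds, applied to a counts matrix
apply_stepwise_mutation <- function(cnt, mu, K) {
  n_mut <- matrix(stats::rbinom(length(cnt), cnt, mu), K)
  if (!any(n_mut > 0L)) return(cnt)
  up <- matrix(stats::rbinom(length(n_mut), n_mut, 0.5), K)
  down <- n_mut - up
  res <- cnt - n_mut
  res[2:K, ] <- res[2:K, ] + up[1:(K - 1L), ]
  res[1:(K - 1L), ] <- res[1:(K - 1L), ] + down[2:K, ]
  # boundary reflections: mutations "off the ends" bounce back
  res[2L, ] <- res[2L, ] + down[1L, ]
  res[K - 1L, ] <- res[K - 1L, ] + up[K, ]
  res
}

# multilocus parametric F_ST from deme allele counts (Hs/Ht form)
fst_from_counts <- function(cnts, two_ne) {
  hs <- ht <- numeric(length(cnts))
  for (j in seq_along(cnts)) {
    P <- cnts[[j]] / two_ne
    hs[j] <- mean(1 - colSums(P^2))
    pbar <- rowMeans(P)
    ht[j] <- 1 - sum(pbar^2)
  }
  if (mean(ht) <= 0) return(NA_real_)
  (mean(ht) - mean(hs)) / mean(ht)
}

#' Decide whether a dataset shows significant population differentiation
#'
#' Runs per-locus genic tests (chi-square or Monte-Carlo exact), combines
#' them across loci with Fisher's method (p floored at 0.0001), and calls
#' the dataset differentiated when the global p-value is below `alpha`.
#'
#' @param ds A [genotypes] object with >= 2 populations.
#' @param alpha Significance level (default 0.05).
#' @param method `"chisq"` or `"exact_mc"`.
#' @param mc_reps Monte-Carlo tables per locus for the exact variant.
#' @param seed Optional integer seed.
#' @return List with `significant` (logical), `p` (global) and `per_locus`.
#' @export
detect_differentiation <- function(ds, alpha = 0.05, method = c("chisq", "exact_mc"),
                                   mc_reps = 2000L, seed = NULL) {
  method <- match.arg(method)
  res <- diff_test(ds, method = method, mc_reps = mc_reps, seed = seed)
  list(significant = is.finite(res$p) && res$p < alpha, p = res$p,
       per_locus = res$per_locus)
}
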