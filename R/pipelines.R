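#' Subsampling (rarefaction) curve of allelic richness vs sample size
#'
#' For each sampling level `S`, individuals are resampled with replacement
#' from the population `reps` times; each resample's mean-over-loci allelic
#' richness is computed at the standardized rarefaction size `g = 2S` gene
#' copies (so resamples with missing data remain comparable), and the curve
#' reports the mean and the 2.5-97.5 percentile band over resamples. A
#' reference value at `S = reference_S` is computed the same way.
#'
#' @param ds A [genotypes] object with a single population, or a
#'   multi-population dataset plus `population`.
#' @param levels Sampling levels (numbers of individuals), default `4:48`.
#' @param reps Resamples per level (default 100).
#' @param seed Optional integer seed.
#' @param population Population label when `ds` has several.
#' @param reference_S Sample size of the dashed reference value
#'   (default 50); `NULL` skips it.
#' @return Object of class `rarefaction_curve`: data frame with columns
#'   `S`, `mean`, `lower`, `upper`, `n_resamples`; attribute `reference`
#'   holds the reference mean.
#' @export
subsample_richness <- function(ds, levels = 4:48, reps = 100L, seed = NULL,
                               population = NULL, reference_S = 50L) {
  stopifnot(inherits(ds, "genotypes"))
  if (!is.null(population)) ds <- subset_populations(ds, population)
  if (length(levels) == 0L) stop("levels must be non-empty")
  n_ind <- length(ds$ids)
  if (n_ind < 2L) stop("population needs >= 2 individuals")
  L <- length(ds$loci)
  one_level <- function(S) {
    vapply(seq_len(reps), function(r) {
      take <- sample.int(n_ind, S, replace = TRUE)
      ar <- vapply(seq_len(L), function(j) {
        x <- c(ds$a1[take, j], ds$a2[take, j])
        x <- x[!is.na(x)]
        if (length(x) == 0L) return(NA_real_)
        cnt <- tabulate(factor(x))
        allelic_richness(cnt[cnt > 0], min(2L * S, length(x)))
      }, numeric(1))
      mean(ar, na.rm = TRUE)
    }, numeric(1))
  }
  with_seed(seed, {
    rows <- lapply(levels, function(S) {
      v <- one_level(S)
      data.frame(S = S, mean = mean(v),
                 lower = unname(stats::quantile(v, 0.025)),
                 upper = unname(stats::quantile(v, 0.975)),
                 n_resamples = reps)
    })
    out <- do.call(rbind, rows)
    if (!is.null(reference_S)) {
      attr(out, "reference") <- mean(one_level(reference_S))
      attr(out, "reference_S") <- reference_S
    }
    class(out) <- c("rarefaction_curve", "data.frame")
    out
  })
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat("Allelic-richness subsampling curve (", x$n_resamples[1L],
      " resamples per level)\n", sep = "")
  if (!is.null(attr(x, "reference"))) {
    cat("Reference A_R at S =", attr(x, "reference_S"), ":",
        round(attr(x, "reference"), 3), "\n")
  }
  print(data.frame(S = x$S, mean = round(x$mean, 3),
                   lower = round(x$lower, 3), upper = round(x$upper, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Power grid for drift-only divergence scenarios
#'
#' For every combination of drift duration `t` and sample size `S`:
#' populations are diverged from the baseline by pure drift
#' ([drift_populations()]), `S` diploids are sampled per population
#' ([sample_genotypes()]), and the global differentiation test
#' ([detect_differentiation()]) is run; power is the fraction of significant
#' replicates. Realized mean Weir-Cockerham theta and Hedrick's G'_ST are
#' recorded per cell so power can be indexed by realized divergence rather
#' than by `t`.
#'
#' @param baseline Baseline frequency pool ([generate_baseline()]).
#' @param t_grid Drift durations in generations.
#' @param S_grid Diploid sample sizes per population.
#' @param n_pops Number of populations (default 14).
#' @param Ne Effective size during drift (default 1000).
#' @param replicates Replicates per cell.
#' @param alpha Significance level.
#' @param method `"chisq"` or `"exact_mc"` per-locus test.
#' @param mc_reps Monte-Carlo tables per locus for the exact variant.
#' @param seed Optional integer seed.
#' @return Object of class `power_grid`: data frame with one row per cell
#'   (`t`, `S`, `expected_fst`, `power`, `mean_theta`, `mean_gprime_st`,
#'   `replicates`, `alpha`).
#' @export
power_drift <- function(baseline, t_grid = c(0L, 2L, 5L, 10L, 15L, 20L, 50L, 102L),
                        S_grid = c(10L, 20L, 30L, 50L), n_pops = 14L, Ne = 1000L,
                        replicates = 1000L, alpha = 0.05,
                        method = c("chisq", "exact_mc"), mc_reps = 2000L,
                        seed = NULL) {
  method <- match.arg(method)
  if (length(t_grid) == 0L || length(S_grid) == 0L) stop("grids must be non-empty")
  cells <- expand.grid(t = t_grid, S = S_grid)
  rows <- vector("list", nrow(cells))
  cell_i <- 0L
  for (ci in seq_len(nrow(cells))) {
    t <- cells$t[ci]; S <- cells$S[ci]
    cell_i <- cell_i + 1L
    sig <- logical(replicates); th <- gp <- numeric(replicates)
    for (r in seq_len(replicates)) {
      rs <- if (is.null(seed)) NULL else derive_seed(seed, cell_i * 1000003L %% 2147483647L + r)
      res <- with_seed(rs, {
        pops <- drift_populations(baseline, n_pops, Ne, t)
        ds <- sample_genotypes(pops, S)
        d <- detect_differentiation(ds, alpha = alpha, method = method,
                                    mc_reps = mc_reps)
        list(sig = d$significant,
             theta = wc_theta(ds)$theta,
             gprime = gst_hedrick(ds)$gprime_st)
      })
      sig[r] <- res$sig; th[r] <- res$theta; gp[r] <- res$gprime
    }
    rows[[ci]] <- data.frame(t = t, S = S, expected_fst = expected_fst(Ne, t),
                             power = mean(sig), mean_theta = mean(th, na.rm = TRUE),
                             mean_gprime_st = mean(gp, na.rm = TRUE),
                             replicates = replicates, alpha = alpha)
  }
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  attr(out, "Ne") <- Ne
  attr(out, "n_pops") <- n_pops
  class(out) <- c("power_grid", "data.frame")
  out
}

#' Power grid for finite-island scenarios
#'
#' For every `(Ne, m, S)` cell, `replicates` island-model datasets are
#' simulated ([island_model_sim()]) and tested
#' ([detect_differentiation()]); power is the significant fraction, and the
#' realized mean theta per cell maps the cell onto a divergence scale.
#'
#' @param Ne_grid Deme effective sizes (default `c(50, 100, 500, 1000)`).
#' @param m_grid Migration rates
#'   (default `c(0.001, 0.005, 0.01, 0.05, 0.1)`).
#' @param S_grid Diploid sample sizes per deme (default `c(10, 20, 30, 50)`).
#' @param n_demes Number of demes (default 10).
#' @param L Loci (default 8).
#' @param mu Stepwise mutation rate (default 5e-4).
#' @param burn_in Burn-in generations; `NULL` for the per-`Ne` default of
#'   [island_model_sim()].
#' @param replicates Replicates per cell.
#' @param alpha Significance level.
#' @param method `"chisq"` or `"exact_mc"`.
#' @param mc_reps Monte-Carlo tables per locus for the exact variant.
#' @param seed Optional integer seed.
#' @return A `power_grid` data frame with columns `Ne`, `m`, `S`, `power`,
#'   `mean_theta`, `replicates`, `alpha`.
#' @export
power_island <- function(Ne_grid = c(50L, 100L, 500L, 1000L),
                         m_grid = c(0.001, 0.005, 0.01, 0.05, 0.1),
                         S_grid = c(10L, 20L, 30L, 50L), n_demes = 10L, L = 8L,
                         mu = 5e-4, burn_in = NULL, replicates = 1000L,
                         alpha = 0.05, method = c("chisq", "exact_mc"),
                         mc_reps = 2000L, seed = NULL) {
  method <- match.arg(method)
  cells <- expand.grid(Ne = Ne_grid, m = m_grid, S = S_grid)
  cells <- cells[cells$S <= cells$Ne, , drop = FALSE]
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    Ne <- cells$Ne[ci]; m <- cells$m[ci]; S <- cells$S[ci]
    sig <- logical(replicates); th <- numeric(replicates)
    for (r in seq_len(replicates)) {
      rs <- if (is.null(seed)) NULL else derive_seed(seed, ci * 999983L %% 2147483647L + r)
      res <- with_seed(rs, {
        ds <- suppressWarnings(
          island_model_sim(n_demes = n_demes, Ne = Ne, m = m, S = S, L = L,
                           mu = mu, burn_in = burn_in, monitor = FALSE))
        d <- detect_differentiation(ds, alpha = alpha, method = method,
                                    mc_reps = mc_reps)
        list(sig = d$significant, theta = wc_theta(ds)$theta)
      })
      sig[r] <- res$sig; th[r] <- res$theta
    }
    rows[[ci]] <- data.frame(Ne = Ne, m = m, S = S, power = mean(sig),
                             mean_theta = mean(th, na.rm = TRUE),
                             replicates = replicates, alpha = alpha)
  }
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  class(out) <- c("power_grid", "data.frame")
  out
}

#' @export
print.power_grid <- function(x, ...) {
  cat("Power grid (", attr(x, "method") %||% "chisq", " per-locus tests, alpha = ",
      x$alpha[1L], ", ", x$replicates[1L], " replicates per cell)\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
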