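#' Weir-Cockerham theta (F_ST estimator)
#'
#' Moment estimator of F_ST from the classic nested variance components:
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals), accumulated over alleles and loci;
#' `theta = sum(a) / sum(a + b + c)`. The multilocus estimate is the ratio of
#' summed components, not the mean of per-locus ratios. Negative estimates
#' are permitted and preserved (they arise in undifferentiated samples
#' because the estimator is unbiased around zero).
#'
#' @param ds A [genotypes] object.
#' @param populations Optional character vector restricting the estimate to
#'   a subset (e.g. one pair) of populations; default all.
#' @return List of class `wc_theta` with `theta` (multilocus), `per_locus`
#'   (named vector, `NA` where a locus is monomorphic across the chosen
#'   populations) and `components` (per-locus sums of `a`, `b`, `c`).
#' @export
wc_theta <- function(ds, populations = NULL) {
  stopifnot(inherits(ds, "genotypes"))
  if (!is.null(populations)) ds <- subset_populations(ds, populations)
  pops <- levels(ds$pop)
  if (length(pops) < 2L) stop("theta requires at least two populations")
  L <- length(ds$loci)
  comp <- matrix(0, L, 3, dimnames = list(ds$loci, c("a", "b", "c")))
  for (j in seq_len(L)) {
    abc <- wc_components_locus(ds$a1[, j], ds$a2[, j], ds$pop)
    if (!is.null(abc)) comp[j, ] <- abc
  }
  denom <- rowSums(comp)
  per_locus <- ifelse(abs(denom) > 0, comp[, "a"] / denom, NA_real_)
  names(per_locus) <- ds$loci
  tot <- colSums(comp)
  theta <- if (abs(sum(tot)) > 0) tot[["a"]] / sum(tot) else NA_real_
  structure(list(theta = theta, per_locus = per_locus, components = comp),
            class = "wc_theta")
}

#' @export
print.wc_theta <- function(x, ...) {
  cat("Weir-Cockerham theta (multilocus):", format(x$theta, digits = 4), "\n")
  cat("Per-locus:\n")
  print(round(x$per_locus, 4))
  invisible(x)
}

# variance components a, b, c summed over alleles for a single locus;
# returns NULL when < 2 populations have data or the locus is monomorphic
wc_components_locus <- function(a1, a2, pop) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]; pop <- droplevels(pop[ok])
  n_j <- tabulate(pop, nbins = nlevels(pop))
  keep <- n_j > 0
  if (sum(keep) < 2L) return(NULL)
  pop <- droplevels(pop)
  n_j <- n_j[keep]
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(c(0, 0, 0))
  r <- length(n_j)
  nbar <- mean(n_j)
  if (nbar <= 1) return(NULL)
  nc <- (r * nbar - sum(n_j^2) / (r * nbar)) / (r - 1)
  A <- 0; B <- 0; C <- 0
  for (al in alleles) {
    cnt <- tapply((a1 == al) + (a2 == al), pop, sum)
    p_j <- cnt / (2 * n_j)
    h_j <- tapply((a1 == al) != (a2 == al), pop, mean)
    pbar <- sum(n_j * p_j) / (r * nbar)
    s2 <- sum(n_j * (p_j - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_j * h_j) / (r * nbar)
    A <- A + nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    B <- B + nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    C <- C + hbar / 2
  }
  c(A, B, C)
}

#' Nei G_ST and Hedrick's standardized G'_ST from frequency vectors
#'
#' The raw (frequency-parameter) statistics for a single locus or a set of
#' loci: \eqn{H_S} is the unweighted mean within-population gene diversity,
#' \eqn{H_T} the gene diversity of the unweighted mean frequencies,
#' \eqn{G_{ST} = (H_T - H_S)/H_T} and Hedrick's rescaling
#' \deqn{G'_{ST} = G_{ST} \frac{k - 1 + H_S}{(k - 1)(1 - H_S)}}
#' which reaches 1 for populations fixed for different alleles regardless of
#' marker polymorphism. For a bias-corrected dataset-level version use
#' [gst_hedrick()].
#'
#' @param freqs For one locus, a list of per-population named frequency
#'   vectors; for several loci, a list of such lists (one element per locus).
#'   Multilocus values average \eqn{H_S} and \eqn{H_T} over loci before
#'   forming the ratios.
#' @return List with `gst`, `gprime_st`, `hs`, `ht`, `k`. `NA` statistics
#'   (with a warning) when `H_T = 0` (all populations monomorphic for the
#'   same allele).
#' @examples
#' hedrick_gprime_st(list(p1 = c(A = 0.75, B = 0.25), p2 = c(A = 0.125, B = 0.875)))
#' @export
hedrick_gprime_st <- function(freqs) {
  if (!is.list(freqs) || length(freqs) == 0L) stop("freqs must be a non-empty list")
  multi <- is.list(freqs[[1L]])
  loci <- if (multi) freqs else list(freqs)
  k <- length(loci[[1L]])
  if (k < 2L) stop("G'_ST requires at least two populations")
  hs_l <- ht_l <- numeric(length(loci))
  for (i in seq_along(loci)) {
    pl <- loci[[i]]
    alleles <- sort(unique(unlist(lapply(pl, names))))
    P <- vapply(pl, function(p) {
      v <- stats::setNames(numeric(length(alleles)), alleles)
      v[names(p)] <- p
      v
    }, numeric(length(alleles)))
    P <- matrix(P, nrow = length(alleles))
    hs_l[i] <- mean(1 - colSums(P^2))
    pbar <- rowMeans(P)
    ht_l[i] <- 1 - sum(pbar^2)
  }
  hs <- mean(hs_l); ht <- mean(ht_l)
  if (ht <= 0) {
    warning("H_T = 0: differentiation undefined")
    return(list(gst = NA_real_, gprime_st = NA_real_, hs = hs, ht = ht, k = k))
  }
  gst <- (ht - hs) / ht
  if (hs >= 1) stop("H_S must be < 1")
  gprime <- gst * (k - 1 + hs) / ((k - 1) * (1 - hs))
  list(gst = gst, gprime_st = gprime, hs = hs, ht = ht, k = k)
}

#' Bias-corrected G_ST and Hedrick's G'_ST from a genotype dataset
#'
#' Dataset-level version applying the Nei-Chesser small-sample corrections:
#' with \eqn{\tilde n} the harmonic mean sample size and \eqn{\bar H_O} the
#' mean observed heterozygosity,
#' \eqn{\hat H_S = \frac{\tilde n}{\tilde n - 1}(1 - \overline{\sum p^2} -
#' \bar H_O / 2\tilde n)} and
#' \eqn{\hat H_T = 1 - \sum \bar p^2 + \hat H_S/(\tilde n k) -
#' \bar H_O/(2 \tilde n k)}. \eqn{H_S}, \eqn{H_T} are averaged over loci
#' before forming \eqn{G_{ST}} and Hedrick's \eqn{G'_{ST}}.
#'
#' @param ds A [genotypes] object.
#' @param populations Optional subset of population labels.
#' @return List with `gst`, `gprime_st`, `hs`, `ht`, `k`, and per-locus
#'   `hs_l`, `ht_l`.
#' @export
gst_hedrick <- function(ds, populations = NULL) {
  stopifnot(inherits(ds, "genotypes"))
  if (!is.null(populations)) ds <- subset_populations(ds, populations)
  pops <- levels(ds$pop)
  k <- length(pops)
  if (k < 2L) stop("G'_ST requires at least two populations")
  hs_l <- ht_l <- rep(NA_real_, length(ds$loci))
  for (j in seq_along(ds$loci)) {
    a1 <- ds$a1[, j]; a2 <- ds$a2[, j]
    ok <- !is.na(a1)
    pop <- droplevels(ds$pop[ok])
    if (nlevels(pop) < 2L) next
    a1 <- a1[ok]; a2 <- a2[ok]
    n_j <- tabulate(pop, nbins = nlevels(pop))
    r <- nlevels(pop)
    ntilde <- r / sum(1 / n_j)
    alleles <- sort(unique(c(a1, a2)))
    P <- vapply(seq_len(r), function(jj) {
      sel <- as.integer(pop) == jj
      cnt <- vapply(alleles, function(al) sum(a1[sel] == al) + sum(a2[sel] == al), numeric(1))
      cnt / (2 * n_j[jj])
    }, numeric(length(alleles)))
    P <- matrix(P, nrow = length(alleles))
    ho <- mean(tapply(a1 != a2, pop, mean))
    hs_raw <- mean(1 - colSums(P^2))
    hs <- ntilde / (ntilde - 1) * (hs_raw - ho / (2 * ntilde))
    pbar <- rowMeans(P)
    ht <- 1 - sum(pbar^2) + hs / (ntilde * r) - ho / (2 * ntilde * r)
    hs_l[j] <- hs; ht_l[j] <- ht
  }
  hs <- mean(hs_l, na.rm = TRUE); ht <- mean(ht_l, na.rm = TRUE)
  if (!is.finite(ht) || ht <= 0) {
    warning("H_T = 0: differentiation undefined")
    return(list(gst = NA_real_, gprime_st = NA_real_, hs = hs, ht = ht, k = k,
                hs_l = hs_l, ht_l = ht_l))
  }
  gst <- (ht - hs) / ht
  gprime <- gst * (k - 1 + hs) / ((k - 1) * (1 - hs))
  list(gst = gst, gprime_st = gprime, hs = hs, ht = ht, k = k,
       hs_l = hs_l, ht_l = ht_l)
}

#' Bootstrap confidence interval for a differentiation statistic
#'
#' Percentile interval for the multilocus statistic, deterministic under a
#' fixed seed. The default resampling unit is loci: per-locus variance
#' components (theta) or per-locus \eqn{H_S}/\eqn{H_T} (G'_ST) are computed
#' once and loci are resampled with replacement, the standard procedure for
#' multilocus F-statistic intervals. Resampling individuals within
#' populations is available (`unit = "individuals"`) but is upward-biased
#' for near-zero differentiation: the duplication noise it injects mimics
#' extra between-population variance, so its intervals do not span zero
#' even for panmictic data.
#'
#' @param ds A [genotypes] object.
#' @param statistic `"theta"` (Weir-Cockerham) or `"gprime_st"` (Hedrick,
#'   Nei-Chesser-corrected).
#' @param reps Bootstrap replicates (>= 100).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @param populations Optional subset of population labels.
#' @param unit Resampling unit, `"loci"` (default) or `"individuals"`.
#' @return List with `lower`, `upper`, `point`, `reps`, `statistic`, `unit`.
#' @export
bootstrap_ci <- function(ds, statistic = c("theta", "gprime_st"), reps = 10000L,
                         level = 0.95, seed = NULL, populations = NULL,
                         unit = c("loci", "individuals")) {
  statistic <- match.arg(statistic)
  unit <- match.arg(unit)
  stopifnot(inherits(ds, "genotypes"))
  if (!is.null(populations)) ds <- subset_populations(ds, populations)
  if (reps < 100L) stop("reps must be >= 100")
  if (any(table(ds$pop) < 2L)) stop("every population needs >= 2 individuals to bootstrap")
  L <- length(ds$loci)
  if (unit == "loci") {
    if (statistic == "theta") {
      fit <- wc_theta(ds)
      comp <- fit$components
      point <- fit$theta
      stat_of <- function(take) {
        tot <- colSums(comp[take, , drop = FALSE])
        if (abs(sum(tot)) > 0) tot[["a"]] / sum(tot) else NA_real_
      }
    } else {
      fit <- gst_hedrick(ds)
      point <- fit$gprime_st
      k <- fit$k
      stat_of <- function(take) {
        hs <- mean(fit$hs_l[take], na.rm = TRUE)
        ht <- mean(fit$ht_l[take], na.rm = TRUE)
        if (!is.finite(ht) || ht <= 0) return(NA_real_)
        (ht - hs) / ht * (k - 1 + hs) / ((k - 1) * (1 - hs))
      }
    }
    vals <- with_seed(seed, {
      vapply(seq_len(reps), function(r)
        stat_of(sample.int(L, replace = TRUE)), numeric(1))
    })
  } else {
    stat_fun <- if (statistic == "theta") function(d) wc_theta(d)$theta
                else function(d) gst_hedrick(d)$gprime_st
    point <- stat_fun(ds)
    idx_by_pop <- split(seq_along(ds$ids), ds$pop)
    vals <- with_seed(seed, {
      vapply(seq_len(reps), function(r) {
        take <- unlist(lapply(idx_by_pop,
                              function(ii) ii[sample.int(length(ii), replace = TRUE)]),
                       use.names = FALSE)
        d <- genotypes(ds$a1[take, , drop = FALSE], ds$a2[take, , drop = FALSE],
                       ds$pop[take], ds$loci)
        stat_fun(d)
      }, numeric(1))
    })
  }
  qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  list(lower = unname(qs[1L]), upper = unname(qs[2L]), point = point,
       reps = reps, statistic = statistic, unit = unit)
}

#' Allele-by-population contingency table at one locus
#'
#' @param ds A [genotypes] object.
#' @param locus Locus name.
#' @param populations Optional subset of population labels.
#' @return Integer matrix of gene-copy counts (alleles x populations).
#' @export
genic_table <- function(ds, locus, populations = NULL) {
  stopifnot(inherits(ds, "genotypes"))
  if (!is.null(populations)) ds <- subset_populations(ds, populations)
  j <- match(locus, ds$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  x <- c(ds$a1[, j], ds$a2[, j])
  p <- factor(rep(as.character(ds$pop), 2L), levels = levels(ds$pop))
  ok <- !is.na(x)
  tab <- table(factor(x[ok]), p[ok])
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  m[, colSums(m) > 0, drop = FALSE]
}

# log probability of a contingency table under fixed margins
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Monte-Carlo exact genic test of population differentiation
#'
#' Tests homogeneity of allele counts across populations on the
#' allele-by-population contingency table of gene copies. Random tables with
#' the observed margins are generated (Patefield algorithm, via
#' [stats::r2dtable()]) and the p-value is the probability-ordering estimate
#' \deqn{p = \frac{1 + \#\{P(\mathrm{sim}) \le P(\mathrm{obs})\}}{\mathrm{reps} + 1}}
#' so `p` is never 0 and always `>= 1/(reps + 1)`.
#'
#' @param x Either a [genotypes] object (then give `locus`) or an integer
#'   contingency table (alleles x populations).
#' @param locus Locus name, when `x` is a dataset.
#' @param populations Optional subset of population labels.
#' @param mc_reps Number of Monte-Carlo tables (default 100000, the
#'   conventional choice for final analyses; power pipelines use fewer).
#' @param seed Optional integer seed.
#' @return The Monte-Carlo p-value. A table with a single allele (no
#'   polymorphism) returns `NA`.
#' @export
exact_genic_test <- function(x, locus = NULL, populations = NULL,
                             mc_reps = 100000L, seed = NULL) {
  tab <- if (inherits(x, "genotypes")) {
    if (is.null(locus)) stop("locus must be given for a genotype dataset")
    genic_table(x, locus, populations)
  } else as.matrix(x)
  if (length(tab) == 0L || sum(tab) == 0L) stop("empty contingency table")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  obs <- log_table_prob(tab)
  with_seed(seed, {
    sims <- stats::r2dtable(mc_reps, rowSums(tab), colSums(tab))
    lp <- vapply(sims, log_table_prob, numeric(1))
    (1 + sum(lp <= obs + 1e-9)) / (mc_reps + 1)
  })
}

#' Chi-square genic test of population differentiation
#'
#' Pearson chi-square on the allele-by-population gene-copy table with
#' `(alleles - 1)(pops - 1)` degrees of freedom (no continuity correction).
#'
#' @inheritParams exact_genic_test
#' @return The p-value (`NA` for a monomorphic table).
#' @export
chisq_genic_test <- function(x, locus = NULL, populations = NULL) {
  tab <- if (inherits(x, "genotypes")) {
    if (is.null(locus)) stop("locus must be given for a genotype dataset")
    genic_table(x, locus, populations)
  } else as.matrix(x)
  if (length(tab) == 0L || sum(tab) == 0L) stop("empty contingency table")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  stats::pchisq(x2, df = (nrow(tab) - 1L) * (ncol(tab) - 1L), lower.tail = FALSE)
}

#' Combine per-locus p-values with Fisher's method
#'
#' Per-locus probabilities are floored at `floor` (default 0.0001) so no
#' single locus can dominate the combined statistic, then
#' \eqn{\chi^2 = -2\sum_l \ln p_l} is referred to a chi-square distribution
#' with `2L` degrees of freedom.
#'
#' @param p_values Numeric vector of per-locus p-values in (0, 1]. `NA`
#'   entries (monomorphic loci) are dropped.
#' @param floor Lower bound applied to each p-value.
#' @return List with `chisq`, `df` and `p` (the global p-value).
#' @export
fisher_combine <- function(p_values, floor = 1e-4) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) stop("no p-values to combine")
  if (any(p_values <= 0) || any(p_values > 1)) stop("p-values must lie in (0, 1]")
  p_values <- pmax(p_values, floor)
  chisq <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Narum-adjusted significance level for multiple testing
#'
#' \eqn{\alpha_{adj} = \alpha / \sum_{i=1}^{k} 1/i}: intermediate in
#' stringency between the Bonferroni correction and no correction, the usual
#' choice for batteries of pairwise differentiation tests.
#'
#' @param alpha Nominal significance level.
#' @param k Number of tests (>= 1).
#' @return The adjusted alpha.
#' @examples
#' narum_adjust(0.05, 91) # 0.009816
#' @export
narum_adjust <- function(alpha = 0.05, k) {
  if (length(k) != 1L || is.na(k) || k < 1) stop("k must be >= 1")
  alpha / sum(1 / seq_len(k))
}

#' Global test of genetic heterogeneity across populations
#'
#' Runs a per-locus genic test (Monte-Carlo exact or chi-square) over all
#' loci and combines the single-locus p-values with Fisher's method
#' (p floored at `floor`).
#'
#' @param ds A [genotypes] object.
#' @param method `"chisq"` or `"exact_mc"`.
#' @param populations Optional subset of population labels.
#' @param mc_reps Monte-Carlo tables per locus for the exact variant.
#' @param floor Per-locus p-value floor for Fisher's method.
#' @param seed Optional integer seed (exact variant only).
#' @return List with `p` (global), `chisq`, `df` and `per_locus` p-values.
#' @export
diff_test <- function(ds, method = c("chisq", "exact_mc"), populations = NULL,
                      mc_reps = 100000L, floor = 1e-4, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "genotypes"))
  if (!is.null(populations)) ds <- subset_populations(ds, populations)
  per_locus <- with_seed(seed, {
    vapply(ds$loci, function(loc) {
      if (method == "chisq") chisq_genic_test(ds, loc)
      else exact_genic_test(ds, loc, mc_reps = mc_reps)
    }, numeric(1))
  })
  comb <- fisher_combine(per_locus, floor = floor)
  c(comb, list(per_locus = per_locus, method = method))
}

#' Pairwise population differentiation matrix
#'
#' Weir-Cockerham theta below the diagonal, Hedrick's G'_ST (Nei-Chesser
#' corrected) above, with per-pair global exact (or chi-square) tests and
#' significance flags at the Narum-adjusted alpha over the `choose(k, 2)`
#' pairs.
#'
#' @param ds A [genotypes] object.
#' @param alpha Nominal significance level before the Narum adjustment.
#' @param method Per-locus test passed to [diff_test()].
#' @param mc_reps Monte-Carlo tables per locus for the exact variant.
#' @param seed Optional integer seed.
#' @return Object of class `pairwise_diff`: list with `matrix` (theta
#'   below / G'_ST above), `p` (pairwise global p-values), `significant`
#'   (logical matrix), `alpha_adj`.
#' @export
pairwise_differentiation <- function(ds, alpha = 0.05, method = c("chisq", "exact_mc"),
                                     mc_reps = 10000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "genotypes"))
  pops <- levels(ds$pop)
  k <- length(pops)
  if (k < 2L) stop("need at least two populations")
  m <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  n_pairs <- choose(k, 2L)
  a_adj <- narum_adjust(alpha, n_pairs)
  pair_i <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      pair_i <- pair_i + 1L
      pair <- c(pops[i], pops[j])
      m[j, i] <- wc_theta(ds, pair)$theta
      m[i, j] <- gst_hedrick(ds, pair)$gprime_st
      ps <- derive_seed(seed %||% 0L, pair_i)
      tst <- diff_test(ds, method = method, populations = pair,
                       mc_reps = mc_reps, seed = if (is.null(seed)) NULL else ps)
      pmat[i, j] <- pmat[j, i] <- tst$p
    }
  }
  structure(list(matrix = m, p = pmat, significant = pmat < a_adj,
                 alpha_adj = a_adj, n_pairs = n_pairs, method = method),
            class = "pairwise_diff")
}

#' @export
print.pairwise_diff <- function(x, digits = 3, ...) {
  cat("Pairwise differentiation: theta below diagonal, G'_ST above\n")
  cat("Narum-adjusted alpha over", x$n_pairs, "pairs:",
      format(x$alpha_adj, digits = 4), "\n\n")
  print(round(x$matrix, digits))
  n_sig <- sum(x$significant[upper.tri(x$significant)], na.rm = TRUE)
  cat("\nSignificant pairs after adjustment:", n_sig, "of", x$n_pairs, "\n")
  invisible(x)
}
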