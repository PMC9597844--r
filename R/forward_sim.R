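#' Life-cycle configuration for the forward simulator
#'
#' Overlapping-generation life cycle of a long-lived, monoecious broadcast
#' spawner: a hard maximum age (`longevity` years, so individuals occupy
#' ages `0..longevity-1`), sexual maturity at `maturity_age` years, random
#' mating without selfing. `longevity = 1, maturity_age = 0` collapses the
#' model to non-overlapping Wright-Fisher generations, the standard
#' validation case.
#'
#' @param longevity Maximum lifespan in years (default 20).
#' @param maturity_age Age at sexual maturity in years (default 2).
#' @return Object of class `life_cycle`.
#' @export
life_cycle <- function(longevity = 20L, maturity_age = 2L) {
  longevity <- as.integer(longevity); maturity_age <- as.integer(maturity_age)
  if (longevity < 1L) stop("longevity must be >= 1 year")
  if (maturity_age < 0L || maturity_age >= longevity)
    stop("maturity_age must satisfy 0 <= maturity_age < longevity")
  structure(list(longevity = longevity, maturity_age = maturity_age),
            class = "life_cycle")
}

#' Initialize a simulated population
#'
#' Creates `N` diploid individuals with uniform random starting ages in
#' `0..longevity-1` (100% generation overlap). Genotypes are drawn either by
#' resampling whole individuals from a source [genotypes] population or by
#' Hardy-Weinberg draws from a baseline frequency list.
#'
#' @param source Either a [genotypes] object (one population used as is, or
#'   pick one via `population`) or a list of per-locus named allele-frequency
#'   vectors (a baseline, e.g. from [generate_baseline()]).
#' @param N Population size (>= 2).
#' @param cfg A [life_cycle] configuration.
#' @param seed Optional integer seed.
#' @param population When `source` is a multi-population dataset, the label
#'   of the population to resample from.
#' @return Population state: list with allele matrices `a1`, `a2`
#'   (`N x loci`), integer `age`, `loci`, and the `cfg`.
#' @export
initialize_population <- function(source, N, cfg = life_cycle(), seed = NULL,
                                  population = NULL) {
  if (N < 2L) stop("N must be >= 2 (no mating possible otherwise)")
  with_seed(seed, {
    if (inherits(source, "genotypes")) {
      ds <- source
      if (!is.null(population)) ds <- subset_populations(ds, population)
      if (length(ds$ids) == 0L) stop("source population is empty")
      take <- sample.int(length(ds$ids), N, replace = TRUE)
      a1 <- ds$a1[take, , drop = FALSE]
      a2 <- ds$a2[take, , drop = FALSE]
      loci <- ds$loci
    } else if (is.list(source) && length(source) > 0L) {
      loci <- names(source) %||% paste0("loc", seq_along(source))
      a1 <- a2 <- matrix(NA_integer_, N, length(source))
      for (j in seq_along(source)) {
        p <- source[[j]]
        sizes <- as.integer(names(p))
        a1[, j] <- sizes[sample.int(length(p), N, replace = TRUE, prob = p)]
        a2[, j] <- sizes[sample.int(length(p), N, replace = TRUE, prob = p)]
      }
      dimnames(a1) <- dimnames(a2) <- list(NULL, loci)
    } else stop("source must be a genotypes object or a per-locus frequency list")
    age <- if (cfg$longevity > 1L) {
      sample.int(cfg$longevity, N, replace = TRUE) - 1L
    } else rep(0L, N)
    list(a1 = a1, a2 = a2, age = age, loci = loci, cfg = cfg)
  })
}

# distinct parent pairs drawn uniformly from the mature pool (no selfing)
draw_parent_pairs <- function(mature_idx, n) {
  if (length(mature_idx) < 2L) stop("fewer than 2 mature individuals available")
  p1 <- mature_idx[sample.int(length(mature_idx), n, replace = TRUE)]
  p2 <- mature_idx[sample.int(length(mature_idx), n, replace = TRUE)]
  clash <- which(p1 == p2)
  while (length(clash)) {
    p2[clash] <- mature_idx[sample.int(length(mature_idx), length(clash), replace = TRUE)]
    clash <- clash[p1[clash] == p2[clash]]
  }
  cbind(p1, p2)
}

#' Advance a simulated population by one year
#'
#' Yearly cycle: ages increment; parents for this year's recruits are drawn
#' from the mature pool (age >= maturity) *before* mortality, i.e.
#' individuals spawn in the year they die; individuals reaching
#' `age >= longevity` die; if the survivor count exceeds `target_N`
#' (a bottleneck year) survivors are culled uniformly at random; recruits
#' (age 0, unable to reproduce this year) are created to restore `target_N`,
#' each from two distinct parents, inheriting one uniformly chosen allele
#' per parent per locus.
#'
#' @param state Population state from [initialize_population()].
#' @param target_N Population size to restore at the end of the year.
#' @return Updated state.
#' @export
advance_year <- function(state, target_N) {
  cfg <- state$cfg
  age <- state$age + 1L
  mature_idx <- which(age >= cfg$maturity_age)
  surv <- which(age < cfg$longevity)
  if (length(surv) > target_N) surv <- sort(sample(surv, target_N))
  n_rec <- target_N - length(surv)
  if (n_rec > 0L) {
    if (length(mature_idx) < 2L)
      stop("fewer than 2 mature individuals; population cannot recruit")
    pr <- draw_parent_pairs(mature_idx, n_rec)
    L <- length(state$loci)
    pick1 <- matrix(stats::runif(n_rec * L) < 0.5, n_rec, L)
    pick2 <- matrix(stats::runif(n_rec * L) < 0.5, n_rec, L)
    c1 <- ifelse(pick1, state$a1[pr[, 1L], , drop = FALSE], state$a2[pr[, 1L], , drop = FALSE])
    c2 <- ifelse(pick2, state$a1[pr[, 2L], , drop = FALSE], state$a2[pr[, 2L], , drop = FALSE])
    state$a1 <- rbind(state$a1[surv, , drop = FALSE], matrix(c1, n_rec, L))
    state$a2 <- rbind(state$a2[surv, , drop = FALSE], matrix(c2, n_rec, L))
    state$age <- c(age[surv], rep(0L, n_rec))
  } else {
    state$a1 <- state$a1[surv, , drop = FALSE]
    state$a2 <- state$a2[surv, , drop = FALSE]
    state$age <- age[surv]
  }
  state
}

# N_A, A_E, H_E, H_O of a population state, averaged over loci
state_metrics <- function(state) {
  L <- length(state$loci)
  na <- ae <- he <- ho <- numeric(L)
  for (j in seq_len(L)) {
    x <- c(state$a1[, j], state$a2[, j])
    cnt <- tabulate(factor(x))
    cnt <- cnt[cnt > 0]
    p <- cnt / sum(cnt)
    na[j] <- length(cnt)
    he[j] <- 1 - sum(p^2)
    ae[j] <- 1 / sum(p^2)
    ho[j] <- mean(state$a1[, j] != state$a2[, j])
  }
  c(n_alleles = mean(na), effective_alleles = mean(ae),
    exp_het = mean(he), obs_het = mean(ho))
}

#' Run a bottleneck scenario of the forward simulator
#'
#' Simulates an isolated, constant-size population for `years` years with
#' overlapping generations: size `N0` at year 0, dropping to `N_post` from
#' `bottleneck_year` onwards. Yearly mean-over-loci `N_A`, `A_E`, `H_E` and
#' `H_O` are averaged over replicates. There is no mutation or migration, so
#' within any replicate the allele set can only shrink.
#'
#' @param source Source of starting genotypes (see [initialize_population()]).
#' @param N0 Initial effective size (default 500).
#' @param N_post Post-bottleneck size (default `N0`, i.e. no bottleneck).
#' @param years Number of simulated years (default 100).
#' @param replicates Number of replicate runs.
#' @param cfg A [life_cycle] configuration.
#' @param bottleneck_year Year at which the size drops (default 1).
#' @param seed Optional integer seed; replicate `r` runs on a seed derived
#'   from `(seed, r)` so results are reproducible and order-independent.
#' @param snapshot_years Years at which to keep per-replicate genotype
#'   snapshots (as [genotypes] objects), e.g. `c(100)`; `NULL` keeps none.
#' @param population Population label when `source` is multi-population.
#' @return Object of class `trajectory_summary`: arrays `mean` and `sd`
#'   (`years+1` rows x 4 metrics) over replicates, `retention` (relative to
#'   year 0), the scenario parameters, and `snapshots` (list by year, each a
#'   list of [genotypes] objects, one per replicate).
#' @export
run_scenario <- function(source, N0 = 500L, N_post = N0, years = 100L,
                         replicates = 1L, cfg = life_cycle(),
                         bottleneck_year = 1L, seed = NULL,
                         snapshot_years = NULL, population = NULL) {
  if (replicates < 1L) stop("replicates must be >= 1")
  if (N_post > N0) stop("N_post must be <= N0")
  metric_names <- c("n_alleles", "effective_alleles", "exp_het", "obs_het")
  acc <- array(NA_real_, c(years + 1L, 4L, replicates),
               dimnames = list(NULL, metric_names, NULL))
  snapshots <- if (is.null(snapshot_years)) NULL else
    stats::setNames(rep(list(vector("list", replicates)), length(snapshot_years)),
                    as.character(snapshot_years))
  for (r in seq_len(replicates)) {
    rs <- if (is.null(seed)) NULL else derive_seed(seed, r)
    acc[, , r] <- with_seed(rs, {
      st <- initialize_population(source, N0, cfg, seed = NULL, population = population)
      out <- matrix(NA_real_, years + 1L, 4L)
      out[1L, ] <- state_metrics(st)
      if (years >= 1L) for (y in seq_len(years)) {
        target <- if (y >= bottleneck_year) N_post else N0
        st <- advance_year(st, target)
        out[y + 1L, ] <- state_metrics(st)
        ylab <- as.character(y)
        if (!is.null(snapshots) && ylab %in% names(snapshots)) {
          snapshots[[ylab]][[r]] <- genotypes(st$a1, st$a2,
                                              rep("sim", nrow(st$a1)), st$loci)
        }
      }
      out
    })
  }
  mean_t <- apply(acc, c(1, 2), mean)
  sd_t <- apply(acc, c(1, 2), stats::sd)
  colnames(mean_t) <- colnames(sd_t) <- metric_names
  retention <- sweep(mean_t, 2L, mean_t[1L, ], "/")
  structure(list(mean = mean_t, sd = sd_t, retention = retention,
                 years = years, replicates = replicates,
                 N0 = N0, N_post = N_post, cfg = cfg, snapshots = snapshots),
            class = "trajectory_summary")
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat("Forward-simulation trajectory: N0 =", x$N0, "-> N =", x$N_post,
      "for", x$years, "years,", x$replicates, "replicates\n")
  yrs <- unique(pmin(x$years, c(0L, 1L, 10L, 25L, 50L, 100L, x$years)))
  cat("Mean metrics (selected years):\n")
  print(round(x$mean[yrs + 1L, , drop = FALSE], 3))
  cat("Retention at final year (relative to year 0):\n")
  print(round(x$retention[x$years + 1L, ], 3))
  invisible(x)
}

#' Retained fraction of a diversity metric relative to year 0
#'
#' @param traj A `trajectory_summary` from [run_scenario()].
#' @param year Year at which to evaluate retention.
#' @param metric One of `"n_alleles"`, `"effective_alleles"`, `"exp_het"`,
#'   `"obs_het"`.
#' @return Ratio of the replicate-mean metric at `year` to its value at
#'   year 0 (`NA` if the year-0 value is 0).
#' @export
retention <- function(traj, year, metric = "n_alleles") {
  stopifnot(inherits(traj, "trajectory_summary"))
  if (year < 0L || year > traj$years) stop("year outside the simulated range")
  metric <- match.arg(metric, colnames(traj$mean))
  base <- traj$mean[1L, metric]
  if (!is.finite(base) || base == 0) return(NA_real_)
  unname(traj$mean[year + 1L, metric] / base)
}
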