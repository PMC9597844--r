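#' Expected heterozygosity (gene diversity)
#'
#' \eqn{H_E = 1 - \sum_i p_i^2} from a vector of allele frequencies.
#'
#' @param freqs Named (or plain) numeric vector of allele frequencies summing
#'   to 1.
#' @return `H_E` in `[0, 1]`.
#' @examples
#' expected_heterozygosity(c(A = 0.5, B = 0.3, C = 0.2)) # 0.62
#' @export
expected_heterozygosity <- function(freqs) {
  check_freqs(freqs)
  1 - sum(freqs^2)
}

check_freqs <- function(freqs) {
  if (length(freqs) == 0L) stop("empty frequency vector")
  if (any(freqs < -1e-12) || any(freqs > 1 + 1e-12)) stop("frequencies must lie in [0, 1]")
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  invisible(TRUE)
}

#' Unbiased expected heterozygosity
#'
#' Nei's small-sample correction for finite sample size:
#' \eqn{uH_E = \frac{2N}{2N-1}(1 - \sum_i p_i^2)} with `N` diploid
#' individuals.
#'
#' @param freqs Allele frequency vector summing to 1.
#' @param n_individuals Number of diploid individuals the frequencies were
#'   estimated from (must be >= 1).
#' @return `uH_E`.
#' @export
unbiased_expected_heterozygosity <- function(freqs, n_individuals) {
  if (length(n_individuals) != 1L || is.na(n_individuals) || n_individuals < 1)
    stop("n_individuals must be a positive count")
  (2 * n_individuals / (2 * n_individuals - 1)) * expected_heterozygosity(freqs)
}

#' Observed heterozygosity at one locus in one population
#'
#' Fraction of non-missing individuals whose two alleles differ.
#'
#' @param ds A [genotypes] object.
#' @param locus Locus name.
#' @param population Population label.
#' @return `H_O`, or `NA` (with a warning) when every call is missing.
#' @export
observed_heterozygosity <- function(ds, locus, population) {
  stopifnot(inherits(ds, "genotypes"))
  j <- match(locus, ds$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  if (!population %in% levels(ds$pop)) stop("unknown population: ", population)
  idx <- ds$pop == population
  a1 <- ds$a1[idx, j]; a2 <- ds$a2[idx, j]
  ok <- !is.na(a1)
  if (!any(ok)) {
    warning("all calls missing at locus ", locus, " in population ", population)
    return(NA_real_)
  }
  mean(a1[ok] != a2[ok])
}

#' Effective number of alleles
#'
#' \eqn{A_E = 1 / \sum_i p_i^2}: the number of equifrequent alleles that
#' would give the same homozygosity.
#'
#' @param freqs Allele frequency vector summing to 1.
#' @return `A_E >= 1`.
#' @export
effective_alleles <- function(freqs) {
  check_freqs(freqs)
  1 / sum(freqs^2)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies drawn without replacement (the standard hypergeometric rarefaction):
#' \deqn{A_R(g) = \sum_i \left[1 - \binom{N - N_i}{g} / \binom{N}{g}\right]}
#' with \eqn{\binom{a}{b} = 0} for \eqn{a < b}. Binomial coefficients are
#' evaluated in log space, so there is no overflow for gene-copy totals in
#' the thousands.
#'
#' @param counts Named integer vector of gene-copy counts per allele.
#' @param g Rarefaction size in gene copies, `1 <= g <= sum(counts)`.
#' @return `A_R(g)`.
#' @examples
#' allelic_richness(c(A = 3, B = 1), g = 2) # 1.5
#' @export
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("empty allele count vector")
  N <- sum(counts)
  if (g < 1) stop("g must be >= 1")
  if (g > N) stop("rarefaction size g = ", g, " exceeds the available ",
                  N, " gene copies")
  # lchoose(a, b) is -Inf for b > a >= 0, so exp() gives the required 0
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Inbreeding coefficient from heterozygosities
#'
#' \eqn{F_{IS} = 1 - H_O / H_E}. Undefined (returns `NA`) at monomorphic
#' loci (`H_E = 0`); population-level values average over the defined loci.
#'
#' @param h_e Expected heterozygosity.
#' @param h_o Observed heterozygosity.
#' @return `F_IS`, or `NA` when `H_E = 0`.
#' @export
inbreeding_coefficient <- function(h_e, h_o) {
  ifelse(h_e > 0, 1 - h_o / h_e, NA_real_)
}

# per-locus metric rows for one population; internal workhorse
locus_metrics <- function(ds, population, g) {
  rows <- lapply(ds$loci, function(loc) {
    cnt <- allele_counts(ds, loc, population)
    n_copies <- sum(cnt)
    if (n_copies == 0L) {
      return(data.frame(population = population, locus = loc, n = 0L,
                        n_alleles = NA_real_, allelic_richness = NA_real_,
                        effective_alleles = NA_real_, exp_het = NA_real_,
                        obs_het = NA_real_, unbiased_exp_het = NA_real_,
                        f_is = NA_real_))
    }
    p <- cnt / n_copies
    he <- 1 - sum(p^2)
    ho <- suppressWarnings(observed_heterozygosity(ds, loc, population))
    n_ind <- n_copies / 2
    data.frame(
      population = population, locus = loc, n = n_ind,
      n_alleles = length(cnt),
      allelic_richness = allelic_richness(cnt, g),
      effective_alleles = 1 / sum(p^2),
      exp_het = he,
      obs_het = ho,
      unbiased_exp_het = (2 * n_ind / (2 * n_ind - 1)) * he,
      f_is = inbreeding_coefficient(he, ho)
    )
  })
  do.call(rbind, rows)
}

#' Within-population diversity summary for one population
#'
#' Per-locus values of the seven standard microsatellite diversity metrics
#' (`N_A`, rarefied `A_R`, `A_E`, `H_E`, `H_O`, `uH_E`, `F_IS`) plus their
#' mean and standard error over loci (SE = sd over loci / sqrt(L), using the
#' sample standard deviation).
#'
#' @param ds A [genotypes] object.
#' @param population Population label.
#' @param g Rarefaction size in gene copies; defaults to the smallest
#'   per-locus gene-copy count of this population.
#' @return List with elements `per_locus` (data frame) and `summary`
#'   (data frame of mean and SE per metric), plus the `g` used.
#' @export
summarize_population <- function(ds, population, g = NULL) {
  stopifnot(inherits(ds, "genotypes"))
  if (!population %in% levels(ds$pop)) stop("unknown population: ", population)
  if (is.null(g)) {
    ns <- vapply(ds$loci, function(loc) sum(allele_counts(ds, loc, population)), numeric(1))
    g <- min(ns[ns > 0])
  }
  per_locus <- locus_metrics(ds, population, g)
  metrics <- c("n_alleles", "allelic_richness", "effective_alleles",
               "exp_het", "obs_het", "unbiased_exp_het", "f_is")
  mu <- vapply(metrics, function(m) mean(per_locus[[m]], na.rm = TRUE), numeric(1))
  se <- vapply(metrics, function(m) {
    v <- per_locus[[m]][!is.na(per_locus[[m]])]
    if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v))
  }, numeric(1))
  list(per_locus = per_locus,
       summary = data.frame(metric = metrics, mean = unname(mu), se = unname(se)),
       g = g)
}

#' Table of within-population diversity metrics, all populations
#'
#' One row per population with `mean +/- SE` over loci for each metric
#' (`A`, `A_R`, `A_E`, `H_E`, `H_O`, `uH_E`, `F_IS`), the shape conventionally
#' reported for microsatellite survey data.
#'
#' @param ds A [genotypes] object.
#' @param g Rarefaction size in gene copies; defaults to the smallest
#'   per-locus gene-copy count across all populations (accounting for
#'   missing data), the standard choice when comparing populations.
#' @return An object of class `diversity_summary`: a data frame with columns
#'   `population`, then `<metric>` and `<metric>_se` pairs; attribute `g`
#'   records the rarefaction size; attribute `per_locus` holds the full
#'   per-locus table.
#' @export
diversity_summary <- function(ds, g = NULL) {
  stopifnot(inherits(ds, "genotypes"))
  pops <- levels(ds$pop)
  if (is.null(g)) {
    ns <- unlist(lapply(pops, function(p)
      vapply(ds$loci, function(loc) sum(allele_counts(ds, loc, p)), numeric(1))))
    ns <- ns[ns > 0]
    if (length(ns) == 0L) stop("no non-missing data in dataset")
    g <- min(ns)
  }
  res <- lapply(pops, function(p) summarize_population(ds, p, g))
  metrics <- c("n_alleles", "allelic_richness", "effective_alleles",
               "exp_het", "obs_het", "unbiased_exp_het", "f_is")
  tab <- data.frame(population = pops)
  for (m in metrics) {
    tab[[m]] <- vapply(res, function(r) r$summary$mean[r$summary$metric == m], numeric(1))
    tab[[paste0(m, "_se")]] <- vapply(res, function(r) r$summary$se[r$summary$metric == m], numeric(1))
  }
  attr(tab, "g") <- g
  attr(tab, "per_locus") <- do.call(rbind, lapply(res, `[[`, "per_locus"))
  class(tab) <- c("diversity_summary", "data.frame")
  tab
}

#' @export
print.diversity_summary <- function(x, digits = 2, ...) {
  cat("Within-population diversity (mean ± SE over loci), rarefaction g =",
      attr(x, "g"), "gene copies\n\n")
  metrics <- c(n_alleles = "A", allelic_richness = "A_R", effective_alleles = "A_E",
               exp_het = "H_E", obs_het = "H_O", unbiased_exp_het = "uH_E", f_is = "F_IS")
  out <- data.frame(population = x$population)
  for (m in names(metrics)) {
    out[[metrics[[m]]]] <- sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                                   x[[m]], x[[paste0(m, "_se")]])
  }
  print(out, row.names = FALSE)
  invisible(x)
}
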