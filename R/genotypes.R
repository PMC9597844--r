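#' Diploid multi-locus genotype dataset
#'
#' Container for diploid microsatellite genotypes grouped by population.
#' Allele codes are positive integers (allele sizes in base pairs); missing
#' calls are `NA`. This is the common currency consumed and produced by the
#' diversity, differentiation and simulation functions.
#'
#' @param a1,a2 Integer matrices (individuals x loci) holding the two allele
#'   codes of each call. The pair is unordered; `NA` in either slot marks the
#'   whole call missing.
#' @param pop Factor (or vector coercible to one) assigning each individual
#'   to exactly one population. Its level order is the population order.
#' @param loci Character vector of locus names (column order of `a1`/`a2`).
#' @param ids Optional character vector of individual labels.
#' @return An object of class `genotypes`.
#' @examples
#' ds <- genotypes(
#'   a1 = matrix(c(101L, 101L, 103L), ncol = 1),
#'   a2 = matrix(c(101L, 103L, 103L), ncol = 1),
#'   pop = c("A", "A", "B"), loci = "loc1"
#' )
#' allele_counts(ds, "loc1", "A")
#' @export
genotypes <- function(a1, a2, pop, loci, ids = NULL) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2))) stop("allele matrices must have identical dimensions")
  if (length(loci) != ncol(a1)) stop("number of locus names must match allele-matrix columns")
  if (length(loci) < 1L) stop("dataset must contain at least one locus")
  if (!is.factor(pop)) pop <- factor(pop, levels = unique(as.character(pop)))
  pop <- droplevels(pop)
  if (length(pop) != nrow(a1)) stop("population assignment must cover every individual")
  if (anyNA(pop)) stop("every individual must belong to exactly one population")
  bad <- (is.na(a1) != is.na(a2))
  if (any(bad)) {
    # half-missing calls are treated as fully missing
    a1[bad] <- NA_integer_
    a2[bad] <- NA_integer_
  }
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE)) {
    stop("allele codes must be positive integers")
  }
  ids <- ids %||% paste0(as.character(pop), "_", stats::ave(seq_along(pop), pop, FUN = seq_along))
  dimnames(a1) <- dimnames(a2) <- list(NULL, loci)
  structure(
    list(a1 = a1, a2 = a2, pop = pop, loci = as.character(loci), ids = as.character(ids)),
    class = "genotypes"
  )
}

#' @export
print.genotypes <- function(x, ...) {
  cat("Diploid genotype dataset:", length(x$ids), "individuals,",
      nlevels(x$pop), "populations,", length(x$loci), "loci\n")
  cat("Populations:", paste(utils::head(levels(x$pop), 8L), collapse = ", "),
      if (nlevels(x$pop) > 8L) "..." else "", "\n")
  cat("Loci:", paste(x$loci, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.genotypes <- function(object, ...) {
  n_by_pop <- table(object$pop)
  miss <- colSums(is.na(object$a1))
  out <- list(n = length(object$ids), n_by_pop = n_by_pop,
              loci = object$loci, missing_by_locus = miss)
  class(out) <- "summary.genotypes"
  out
}

#' @export
print.summary.genotypes <- function(x, ...) {
  cat("Individuals:", x$n, "\n")
  cat("Per-population sample sizes:\n")
  print(x$n_by_pop)
  cat("Missing calls per locus:\n")
  print(x$missing_by_locus)
  invisible(x)
}

#' Number of populations / loci in a genotype dataset
#' @param ds A `genotypes` object.
#' @return Integer count.
#' @export
n_populations <- function(ds) nlevels(ds$pop)

#' @rdname n_populations
#' @export
n_loci <- function(ds) length(ds$loci)

#' Population labels of a genotype dataset
#' @param ds A `genotypes` object.
#' @return Character vector of population labels in dataset order.
#' @export
population_names <- function(ds) levels(ds$pop)

#' Subset a genotype dataset by population
#' @param ds A `genotypes` object.
#' @param pops Character vector of population labels to keep.
#' @return A `genotypes` object restricted to `pops`.
#' @export
subset_populations <- function(ds, pops) {
  missing_pops <- setdiff(pops, levels(ds$pop))
  if (length(missing_pops)) stop("unknown population(s): ", paste(missing_pops, collapse = ", "))
  keep <- ds$pop %in% pops
  genotypes(ds$a1[keep, , drop = FALSE], ds$a2[keep, , drop = FALSE],
            factor(as.character(ds$pop[keep]), levels = pops),
            ds$loci, ds$ids[keep])
}

#' Read a Genepop file
#'
#' Parses the classic Genepop text format: a title line, a locus list (either
#' one locus per line or a single comma-separated line), then `POP`-delimited
#' blocks of individuals written as `id , 0102 0304 ...`. Both 2-digit and
#' 3-digit allele encodings are auto-detected; all-zero codes (`0000`,
#' `000000`) decode as missing. The population label is taken from text after
#' the `POP` keyword if present, otherwise from the identifier of the last
#' individual of the block (the conventional Genepop habit), de-duplicated
#' if necessary.
#'
#' @param path Path to a Genepop file.
#' @return A [genotypes] object.
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\ufeff", "", lines)
  if (length(lines) < 3L) stop("not a Genepop file (fewer than 3 lines): ", path)
  is_pop <- toupper(trimws(lines)) == "POP" |
    grepl("^\\s*POP\\b", lines, ignore.case = TRUE) &
      !grepl(",", lines)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("no POP line found in ", path)
  if (first_pop <= 2L) stop("zero loci declared in ", path)
  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("zero loci declared in ", path)

  pop_starts <- which(is_pop)
  pop_starts <- pop_starts[pop_starts >= first_pop]
  bounds <- c(pop_starts, length(lines) + 1L)
  n_loci <- length(loci)
  a1_all <- list(); a2_all <- list(); ids <- character(); pop_of <- character()
  pop_labels <- character(length(pop_starts))

  for (b in seq_along(pop_starts)) {
    hdr <- trimws(lines[pop_starts[b]])
    tag <- trimws(sub("^\\s*POP\\b", "", hdr, ignore.case = TRUE))
    block <- lines[(pop_starts[b] + 1L):(bounds[b + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    if (length(block) == 0L) stop("empty population block ", b, " in ", path)
    last_id <- NA_character_
    for (k in seq_along(block)) {
      line_no <- pop_starts[b] + k  # approximate: blanks inside blocks are rare
      parts <- strsplit(block[k], ",", fixed = TRUE)[[1]]
      if (length(parts) < 2L) stop("missing ',' separator at line ", line_no, " of ", path)
      id <- trimws(parts[1L])
      fields <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1]]
      fields <- fields[nzchar(fields)]
      if (length(fields) != n_loci) {
        stop("expected ", n_loci, " genotype fields, found ", length(fields),
             " at line ", line_no, " of ", path)
      }
      w <- nchar(fields)
      if (any(w %% 2L != 0L) || !all(w %in% c(4L, 6L))) {
        stop("malformed genotype field (odd or unsupported digit count) at line ",
             line_no, " of ", path)
      }
      dg <- w[1L] / 2L
      if (any(w != w[1L])) stop("inconsistent allele digit widths at line ", line_no, " of ", path)
      x1 <- as.integer(substr(fields, 1L, dg))
      x2 <- as.integer(substr(fields, dg + 1L, 2L * dg))
      x1[x1 == 0L] <- NA_integer_
      x2[x2 == 0L] <- NA_integer_
      a1_all[[length(a1_all) + 1L]] <- x1
      a2_all[[length(a2_all) + 1L]] <- x2
      ids <- c(ids, id)
      last_id <- id
      pop_of <- c(pop_of, sprintf("block%03d", b))
    }
    pop_labels[b] <- if (nzchar(tag)) tag else last_id
  }
  pop_labels[!nzchar(pop_labels)] <- paste0("pop_", which(!nzchar(pop_labels)))
  pop_labels <- make.unique(pop_labels, sep = "_")
  pop <- factor(pop_of, levels = sprintf("block%03d", seq_along(pop_starts)),
                labels = pop_labels)
  genotypes(do.call(rbind, a1_all), do.call(rbind, a2_all), pop, loci, ids)
}

#' Write a Genepop file
#'
#' Emits the dataset in Genepop text format with a deterministic ordering:
#' populations, then individuals, then loci exactly as stored. Locus names
#' are written one per line; missing calls are encoded as all-zero codes.
#' The output is re-readable by [read_genepop()].
#'
#' @param ds A [genotypes] object.
#' @param path Output file path.
#' @param digits Allele code width, 2 or 3. All allele codes must be
#'   `< 10^digits`.
#' @param title Title line; defaults to a short description of the dataset.
#' @return Invisibly, `path`.
#' @export
write_genepop <- function(ds, path, digits = 3L, title = NULL) {
  stopifnot(inherits(ds, "genotypes"))
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3")
  if (nlevels(ds$pop) == 0L || length(ds$ids) == 0L) stop("dataset has no populations")
  mx <- suppressWarnings(max(ds$a1, ds$a2, na.rm = TRUE))
  if (is.finite(mx) && mx >= 10^digits) {
    stop("allele code ", mx, " does not fit in ", digits, "-digit encoding")
  }
  fmt <- function(m) {
    z <- formatC(m, width = digits, flag = "0")
    z[is.na(m)] <- strrep("0", digits)
    z
  }
  e1 <- fmt(ds$a1); e2 <- fmt(ds$a2)
  out <- c(title %||% paste("msatpower dataset:", nlevels(ds$pop), "populations,",
                            length(ds$loci), "loci"),
           ds$loci)
  for (p in levels(ds$pop)) {
    out <- c(out, paste("POP", p))
    idx <- which(ds$pop == p)
    for (i in idx) {
      out <- c(out, paste0(ds$ids[i], " ,  ",
                           paste(paste0(e1[i, ], e2[i, ]), collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Gene-copy counts of every allele at one locus in one population
#'
#' @param ds A [genotypes] object.
#' @param locus Locus name.
#' @param population Population label.
#' @return Named integer vector mapping allele code to gene-copy count
#'   (sums to twice the number of non-missing individuals). Empty when every
#'   call is missing.
#' @export
allele_counts <- function(ds, locus, population) {
  stopifnot(inherits(ds, "genotypes"))
  j <- match(locus, ds$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  if (!population %in% levels(ds$pop)) stop("unknown population: ", population)
  idx <- ds$pop == population
  x <- c(ds$a1[idx, j], ds$a2[idx, j])
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-population, per-locus allele frequency table
#'
#' @param ds A [genotypes] object.
#' @return An object of class `freq_table`: `freq[[locus]][[population]]` is
#'   a named numeric vector of allele frequencies (empty when the cell has no
#'   data) and `n[population, locus]` the gene-copy count behind it.
#' @export
to_frequencies <- function(ds) {
  stopifnot(inherits(ds, "genotypes"))
  if (length(ds$ids) == 0L) stop("dataset is empty")
  pops <- levels(ds$pop)
  n <- matrix(0L, length(pops), length(ds$loci), dimnames = list(pops, ds$loci))
  freq <- stats::setNames(vector("list", length(ds$loci)), ds$loci)
  for (loc in ds$loci) {
    freq[[loc]] <- stats::setNames(vector("list", length(pops)), pops)
    for (p in pops) {
      cnt <- allele_counts(ds, loc, p)
      n[p, loc] <- sum(cnt)
      freq[[loc]][[p]] <- if (sum(cnt) > 0L) cnt / sum(cnt) else stats::setNames(numeric(0), character(0))
    }
  }
  structure(list(freq = freq, n = n, populations = pops, loci = ds$loci),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("Allele frequency table:", length(x$populations), "populations x",
      length(x$loci), "loci\n")
  cat("Gene-copy counts (n):\n")
  print(x$n)
  invisible(x)
}
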