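#' @include population.R
NULL

#' True (IBD-based) inbreeding coefficients
#'
#' The fraction of IBD tracer loci at which an animal's two allele labels
#' are identical, i.e. trace back to the same base-population haplotype.
#' Base animals are 0 by construction.
#'
#' @param pop a [BreedingPop-class].
#' @param ids animal ids (default all).
#' @return named numeric vector of coefficients in [0, 1].
#' @export
trueInbreeding <- function(pop, ids = pop@ped$id) {
  rows <- match(ids, pop@ped$id)
  f <- rowMeans(pop@I1[rows, , drop = FALSE] ==
                pop@I2[rows, , drop = FALSE])
  names(f) <- as.character(ids)
  f
}

#' Pedigree inbreeding coefficients (Wright, tabular method)
#'
#' Computes the numerator relationship matrix by the tabular method over a
#' pedigree sorted so parents precede offspring, and returns F = diag(A) - 1
#' relative to the (assumed unrelated, non-inbred) base animals.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (0 = unknown);
#'   parents must appear before their offspring.
#' @return named numeric vector of inbreeding coefficients.
#' @export
pedigreeInbreeding <- function(ped) {
  n <- nrow(ped)
  s <- match(ped$sire, ped$id, nomatch = 0L)
  d <- match(ped$dam, ped$id, nomatch = 0L)
  if (any(s >= seq_len(n) & s > 0L) || any(d >= seq_len(n) & d > 0L))
    stop("pedigree must be sorted with parents before offspring (acyclic)")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (si > 0L) A[j, si] else 0) +
                    (if (di > 0L) A[j, di] else 0))
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  f <- diag(A) - 1
  names(f) <- as.character(ped$id)
  f
}

#' Rate of genetic gain
#'
#' Ordinary least-squares slope of the mean true genetic value of animals
#' born in generation t on t, over the evaluation span.
#'
#' @param meanTbv numeric per-generation means.
#' @param gens the generation indices (default: positions).
#' @return the slope (trait units per generation).
#' @export
rateOfGain <- function(meanTbv, gens = seq_along(meanTbv)) {
  if (length(meanTbv) < 3L) stop("need at least 3 generations")
  unname(coef(lm(meanTbv ~ gens))[2L])
}

#' Rate of inbreeding
#'
#' 1 - exp(beta) where beta is the OLS slope of ln(1 - F_t) on t; F_t is
#' the mean (true or pedigree) inbreeding of animals born in generation t.
#' Exact for geometric series F_t = 1 - (1 - dF)^t.
#'
#' @param meanF numeric per-generation mean inbreeding, all < 1.
#' @param gens generation indices.
#' @return the per-generation rate of inbreeding.
#' @export
rateOfInbreeding <- function(meanF, gens = seq_along(meanF)) {
  if (length(meanF) < 3L) stop("need at least 3 generations")
  if (any(meanF >= 1)) stop("F = 1 reached; log(1 - F) undefined")
  beta <- unname(coef(lm(log(1 - meanF) ~ gens))[2L])
  1 - exp(beta)
}

#' Aggregate replicate summaries
#'
#' Means and standard errors (sd / sqrt(R)) of each numeric column across
#' replicates, per scenario grouping.
#'
#' @param reps data.frame of replicate summaries; non-numeric columns are
#'   treated as grouping keys.
#' @return data.frame with one row per group and `<col>` / `<col>_se`
#'   columns.
#' @export
aggregateReplicates <- function(reps) {
  num <- vapply(reps, is.numeric, logical(1))
  keys <- names(reps)[!num]
  vals <- names(reps)[num]
  if (length(reps[vals]) == 0L) stop("no numeric metric columns")
  grp <- if (length(keys)) interaction(reps[keys], drop = TRUE)
         else factor(rep(1, nrow(reps)))
  out <- NULL
  for (g in levels(grp)) {
    sub <- reps[grp == g, , drop = FALSE]
    row <- if (length(keys)) sub[1L, keys, drop = FALSE] else data.frame(row.names = 1L)
    for (v in vals) {
      row[[v]] <- mean(sub[[v]])
      row[[paste0(v, "_se")]] <- if (nrow(sub) > 1L)
        sd(sub[[v]]) / sqrt(nrow(sub)) else 0
    }
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

#' Relative advantage of one scenario over another, in percent
#'
#' `100 * (a / b - 1)`: e.g. the percent extra rate of genetic gain of one
#' matrix combination over another at a matched rate of true inbreeding,
#' or the percent extra prediction accuracy.
#'
#' @param a,b numeric values (focal, reference).
#' @return percent advantage.
#' @export
advantagePct <- function(a, b) 100 * (a / b - 1)

#' Advantage of a focal scenario over a set of alternatives
#'
#' Computes the percent advantage of the focal scenario's metric over each
#' alternative and returns the per-alternative values with their min and
#' max (the bounds usually quoted for "between x and y percent more
#' gain").
#'
#' @param tbl data.frame with a scenario key column and a metric column.
#' @param focal focal scenario name.
#' @param alternatives alternative scenario names.
#' @param metric metric column name.
#' @param key scenario key column name (default "scenario").
#' @return list: `byAlternative` (named percent advantages), `min`, `max`.
#' @export
scenarioAdvantage <- function(tbl, focal, alternatives, metric,
                              key = "scenario") {
  stopifnot(metric %in% names(tbl), key %in% names(tbl))
  val <- function(s) {
    i <- match(s, tbl[[key]])
    if (is.na(i)) stop("scenario not in table: ", s)
    tbl[[metric]][i]
  }
  adv <- vapply(alternatives, function(s) advantagePct(val(focal), val(s)),
                numeric(1))
  names(adv) <- alternatives
  list(byAlternative = adv, min = min(adv), max = max(adv))
}
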