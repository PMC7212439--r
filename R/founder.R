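#' @include genome.R
#' @include meiosis.R
NULL

#' Founder population pools
#'
#' Result of the historical Wright-Fisher founder simulation: the final
#' generation's haplotypes (the per-chromosome pools that seed base
#' populations), the table of segregating loci with current derived-allele
#' frequencies, and raw (unstandardized) QTL effects.
#'
#' Haplotypes `2i-1` and `2i` belong to founder animal `i`; base-population
#' sampling treats each chromosome's 2N haplotypes as an independent pool.
#'
#' @slot spec the [GenomeSpec-class] used.
#' @slot haps list of 2N sorted integer vectors of derived-allele locus ids.
#' @slot loci data.frame over segregating loci: `locus`, `chrom`, `posCM`,
#'   `class` ("marker"/"qtl"), `freq`, `rawEffect` (0 for markers).
#' @slot popSize integer N (number of founder animals).
#' @export
setClass("FounderPools", representation(
  spec = "GenomeSpec", haps = "list", loci = "data.frame",
  popSize = "integer"))

setValidity("FounderPools", function(object) {
  msg <- character()
  if (length(object@haps) != 2L * object@popSize)
    msg <- c(msg, "need two haplotypes per founder animal")
  need <- c("locus", "chrom", "posCM", "class", "freq", "rawEffect")
  if (!all(need %in% names(object@loci)))
    msg <- c(msg, "loci table missing required columns")
  if (nrow(object@loci) &&
      (any(object@loci$freq <= 0) || any(object@loci$freq >= 1)))
    msg <- c(msg, "segregating-locus frequencies must lie in (0,1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FounderPools", function(object) {
  cat("FounderPools:", object@popSize, "animals,",
      nrow(object@loci), "segregating loci (",
      sum(object@loci$class == "qtl"), "QTL,",
      sum(object@loci$class == "marker"), "marker)\n")
})

#' @describeIn FounderPools-class Segregating-loci table.
#' @param pools a [FounderPools-class].
#' @export
segregatingLoci <- function(pools) pools@loci

#' Sample raw additive effects for mutant QTL alleles
#'
#' Effect magnitudes are Exponential(rate = 1/scale); the sign is positive
#' with probability `posProb` (default 0.1), otherwise negative. The
#' non-mutant allele has effect 0. Effects are later standardized so the
#' founder-population additive variance is 1.
#'
#' @param n number of effects.
#' @param posProb probability an effect is positive.
#' @param scale exponential scale (mean magnitude) before standardization.
#' @return numeric vector of signed effects.
#' @export
sampleQtlEffects <- function(n, posProb = 0.1, scale = 1) {
  if (n == 0L) return(numeric())
  mag <- rexp(n, rate = 1 / scale)
  sgn <- ifelse(runif(n) < posProb, 1, -1)
  mag * sgn
}

## TBV of sparse diploids given a dense per-locus effect vector
sparseTbv <- function(haps, effect) {
  n <- length(haps) / 2L
  vapply(seq_len(n), function(i) {
    sum(effect[haps[[2L * i - 1L]]]) + sum(effect[haps[[2L * i]]])
  }, numeric(1))
}

## drop loci (e.g. fixed ones) from every haplotype
dropLociFromHaps <- function(haps, drop) {
  if (!length(drop)) return(haps)
  lapply(haps, function(h) h[!(h %in% drop)])
}

#' Run the historical founder simulation
#'
#' Simulates `nGenerations` discrete Wright-Fisher generations of a
#' population of `popSize` animals (half male, half female) under mutation,
#' recombination, drift, and mild directional selection: in each generation
#' the `ceiling(cullFraction * popSize)` offspring with the lowest true
#' breeding value are culled and replaced by newly sampled offspring (one
#' pass; replacements are not re-culled). Parents are sampled with
#' replacement from the previous generation's males and females.
#'
#' Mutation converts never-mutated candidate loci to carry the derived
#' allele on one gamete; a QTL-class locus (probability `qtlFraction`)
#' receives a raw effect from [sampleQtlEffects()] at first mutation.
#' Loci fixed for the derived allele are dropped (they contribute a
#' constant to every TBV); lost loci simply disappear.
#'
#' @param spec a [GenomeSpec-class].
#' @param nGenerations number of discrete generations (>= 1).
#' @param popSize even census size (paper-scale study: 50, i.e. Ne = 50).
#' @param cullFraction fraction of each generation culled for low TBV.
#' @param effectPosProb probability a QTL effect is positive.
#' @return A [FounderPools-class].
#' @export
runFounder <- function(spec, nGenerations, popSize = 50L,
                       cullFraction = 0.05, effectPosProb = 0.1) {
  stopifnot(nGenerations >= 1L, popSize >= 2L)
  if (popSize %% 2L != 0L) stop("popSize must be even (equal sexes)")
  N <- as.integer(popSize)
  nL <- nLoci(spec)
  if (nL > 5e7) stop("candidate-locus count too large to instantiate")

  effect <- numeric(nL)            # raw effect per locus (0 = marker/none)
  isQtl <- logical(nL)
  pool <- seq_len(nL)              # never-mutated loci
  males <- seq_len(N / 2L)
  females <- (N / 2L + 1L):N

  haps <- rep(list(integer()), 2L * N)

  newOffspring <- function(curHaps) {
    sire <- sample(males, 1L)
    dam <- sample(females, 1L)
    g1 <- meiosis(curHaps[[2L * sire - 1L]], curHaps[[2L * sire]], spec)
    g2 <- meiosis(curHaps[[2L * dam - 1L]], curHaps[[2L * dam]], spec)
    m1 <- mutateGamete(g1, pool, spec@mutationRate)
    if (length(m1$newLoci)) pool <<- pool[!(pool %in% m1$newLoci)]
    m2 <- mutateGamete(g2, pool, spec@mutationRate)
    if (length(m2$newLoci)) pool <<- pool[!(pool %in% m2$newLoci)]
    newLoci <- c(m1$newLoci, m2$newLoci)
    if (length(newLoci)) {
      q <- runif(length(newLoci)) < spec@qtlFraction
      if (any(q)) {
        ql <- newLoci[q]
        isQtl[ql] <<- TRUE
        effect[ql] <<- sampleQtlEffects(sum(q), posProb = effectPosProb)
      }
    }
    list(as.vector(m1$gamete), as.vector(m2$gamete))
  }

  for (gen in seq_len(nGenerations)) {
    off <- vector("list", 2L * N)
    for (i in seq_len(N)) {
      g <- newOffspring(haps)
      off[[2L * i - 1L]] <- g[[1L]]
      off[[2L * i]] <- g[[2L]]
    }
    if (cullFraction > 0) {
      tbv <- sparseTbv(off, effect)
      nCull <- min(N, ceiling(cullFraction * N))
      worst <- order(tbv, runif(N))[seq_len(nCull)]   # random tie-break
      for (i in worst) {
        g <- newOffspring(haps)
        off[[2L * i - 1L]] <- g[[1L]]
        off[[2L * i]] <- g[[2L]]
      }
    }
    haps <- off
    ## drop loci fixed for the derived allele (constant in every TBV)
    cnt <- tabulate(unlist(haps, use.names = FALSE), nbins = nL)
    fixed <- which(cnt == 2L * N)
    if (length(fixed)) haps <- dropLociFromHaps(haps, fixed)
  }

  cnt <- tabulate(unlist(haps, use.names = FALSE), nbins = nL)
  seg <- which(cnt > 0L & cnt < 2L * N)
  if (!length(seg))
    stop("no segregating loci at the end of the founder simulation; ",
         "increase the mutation rate or the number of generations")
  loci <- data.frame(
    locus = seg,
    chrom = locusChrom(spec, seg),
    posCM = locusPosCM(spec, seg),
    class = ifelse(isQtl[seg], "qtl", "marker"),
    freq = cnt[seg] / (2L * N),
    rawEffect = effect[seg],
    stringsAsFactors = FALSE)
  new("FounderPools", spec = spec, haps = haps, loci = loci,
      popSize = N)
}

#' Dense dosage matrix of the founder animals at given loci
#'
#' @param pools a [FounderPools-class].
#' @param lociIds genome-wide locus ids (default: all segregating loci).
#' @return integer matrix, founder animals x loci, entries 0/1/2.
#' @export
founderDosage <- function(pools, lociIds = segregatingLoci(pools)$locus) {
  n <- pools@popSize
  out <- matrix(0L, n, length(lociIds))
  for (i in seq_len(n)) {
    h <- c(pools@haps[[2L * i - 1L]], pools@haps[[2L * i]])
    t <- tabulate(match(h, lociIds), nbins = length(lociIds))
    out[i, ] <- t
  }
  rownames(out) <- paste0("F", seq_len(n))
  colnames(out) <- as.character(lociIds)
  out
}

## dense 0/1 haplotype matrix (2N x loci) for the pools at given loci
founderHapMatrix <- function(pools, lociIds) {
  m <- matrix(0L, length(pools@haps), length(lociIds))
  for (j in seq_along(pools@haps)) {
    hit <- match(pools@haps[[j]], lociIds)
    hit <- hit[!is.na(hit)]
    m[j, hit] <- 1L
  }
  colnames(m) <- as.character(lociIds)
  m
}
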