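#' @include genome.R
NULL

## Recombination machinery.
##
## A meiosis is described by a "recombination pattern": the genome-wide
## crossover count is Poisson(genome length in Morgans), crossover positions
## are uniform on the genetic map (no interference), and each chromosome
## starts from one of the two parental haplotypes with probability 1/2.
## The same pattern object is applied to sparse haplotypes (founder phase)
## and to dense allele/IBD-label rows (breeding-scheme phase), so the two
## representations transmit identically.

#' Sample a recombination pattern for one meiosis
#'
#' Draws the crossover count from Poisson(lambda) with lambda the genome
#' length in Morgans, places crossovers uniformly on the genetic map, and
#' chooses the starting parental haplotype per chromosome with probability
#' 1/2. Consumes the R random number stream.
#'
#' @param spec a [GenomeSpec-class].
#' @return A list with `breaks` (per-chromosome sorted crossover positions,
#'   cM) and `start` (per-chromosome 0/1 starting haplotype).
#' @export
sampleRecombination <- function(spec) {
  lambda <- genomeLengthMorgans(spec)
  n <- rpois(1L, lambda)
  pos <- sort(runif(n, 0, genomeLengthCM(spec)))
  bounds <- c(0, cumsum(spec@chromLengthCM))
  chr <- findInterval(pos, bounds, rightmost.closed = TRUE)
  chr[chr > spec@nChromosomes] <- spec@nChromosomes
  breaks <- lapply(seq_len(spec@nChromosomes), function(c)
    pos[chr == c] - bounds[c])
  start <- sample(c(0L, 1L), spec@nChromosomes, replace = TRUE)
  list(breaks = breaks, start = start, nCrossovers = n)
}

## Source haplotype (0 = first parental, 1 = second) for loci at the given
## chromosome / position (cM within chromosome).
recombSource <- function(pattern, chrom, posCM) {
  src <- integer(length(chrom))
  for (c in unique(chrom)) {
    i <- which(chrom == c)
    src[i] <- (pattern$start[c] + findInterval(posCM[i], pattern$breaks[[c]])) %% 2L
  }
  src
}

## Apply a pattern to two sparse haplotypes (sorted genome-wide locus ids):
## keep hapA loci falling in source-0 segments and hapB loci in source-1.
applyRecombSparse <- function(pattern, spec, hapA, hapB) {
  keepA <- if (length(hapA))
    hapA[recombSource(pattern, locusChrom(spec, hapA), locusPosCM(spec, hapA)) == 0L]
  else integer()
  keepB <- if (length(hapB))
    hapB[recombSource(pattern, locusChrom(spec, hapB), locusPosCM(spec, hapB)) == 1L]
  else integer()
  sort(c(keepA, keepB))
}

## Apply a pattern to dense rows (alleles or IBD labels) over loci with
## known chromosome/position; src may be precomputed and shared.
applyRecombDense <- function(src, rowA, rowB) {
  out <- rowA
  sel <- src == 1L
  out[sel] <- rowB[sel]
  out
}

#' One gamete by meiosis from a sparse diploid parent
#'
#' @param hapA,hapB the parent's two haplotypes: sorted integer vectors of
#'   genome-wide candidate-locus ids carrying the derived allele.
#' @param spec a [GenomeSpec-class].
#' @return A sorted integer vector of locus ids (the gamete), with attribute
#'   `nCrossovers`.
#' @export
meiosis <- function(hapA, hapB, spec) {
  pat <- sampleRecombination(spec)
  g <- applyRecombSparse(pat, spec, hapA, hapB)
  attr(g, "nCrossovers") <- pat$nCrossovers
  g
}

#' Add new mutations to a gamete
#'
#' The number of new mutations is Binomial(n, mu) over the pool of
#' never-mutated candidate loci; mutated loci are drawn uniformly without
#' replacement from the pool. Pool bookkeeping (removal of the returned
#' loci) is the caller's responsibility.
#'
#' @param gamete sorted integer vector of derived-allele locus ids.
#' @param pool integer vector of currently monomorphic (never-mutated)
#'   candidate-locus ids.
#' @param mutationRate per-locus per-gamete mutation probability.
#' @return A list: `gamete` (with mutations added) and `newLoci` (the
#'   mutated locus ids).
#' @export
mutateGamete <- function(gamete, pool, mutationRate) {
  if (mutationRate <= 0 || length(pool) == 0L)
    return(list(gamete = gamete, newLoci = integer()))
  n <- rbinom(1L, length(pool), mutationRate)
  if (n == 0L)
    return(list(gamete = gamete, newLoci = integer()))
  newLoci <- pool[sample.int(length(pool), n)]
  list(gamete = sort(c(gamete, newLoci)), newLoci = newLoci)
}
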