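#' @import methods
#' @importFrom stats rbinom rpois runif rnorm rexp var cor lm coef sd
#'   quantile setNames aggregate
#' @importFrom utils head tail write.table read.table
NULL

#' Genome specification
#'
#' Describes the simulated genome: chromosome number and genetic lengths,
#' the density of candidate (mutable) loci, the fraction of candidate loci
#' that are QTL-class, the per-locus per-gamete mutation rate, and the
#' density of neutral identity-by-descent (IBD) tracer loci.
#'
#' Candidate loci are equidistant on the genetic map; locus `k` of a
#' chromosome sits at `(k - 0.5) / lociPerCM` cM. All densities are per cM.
#'
#' @slot nChromosomes integer, number of autosomes.
#' @slot chromLengthCM numeric vector of chromosome lengths in cM.
#' @slot lociPerCM numeric, density of candidate loci.
#' @slot qtlFraction numeric in (0,1), fraction of candidate loci that are
#'   QTL-class.
#' @slot mutationRate numeric, per-locus per-gamete mutation probability.
#' @slot ibdLociPerCM numeric, density of IBD tracer loci.
#' @export
setClass("GenomeSpec", representation(
  nChromosomes = "integer",
  chromLengthCM = "numeric",
  lociPerCM = "numeric",
  qtlFraction = "numeric",
  mutationRate = "numeric",
  ibdLociPerCM = "numeric"
))

setValidity("GenomeSpec", function(object) {
  msg <- character()
  if (object@nChromosomes < 1L)
    msg <- c(msg, "need at least one chromosome")
  if (length(object@chromLengthCM) != object@nChromosomes)
    msg <- c(msg, "chromLengthCM must have one entry per chromosome")
  if (any(object@chromLengthCM <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (object@lociPerCM <= 0 || object@ibdLociPerCM <= 0)
    msg <- c(msg, "locus densities must be positive")
  if (object@qtlFraction <= 0 || object@qtlFraction >= 1)
    msg <- c(msg, "qtlFraction must lie in (0,1)")
  if (object@mutationRate < 0 || object@mutationRate > 1)
    msg <- c(msg, "mutationRate must be a probability")
  if (length(msg)) msg else TRUE
})

#' Construct a genome specification
#'
#' Defaults reproduce the full-scale study genome: 18 chromosomes of 167 cM
#' (3006 cM, 30.06 Morgans), 10^4 candidate loci per cM (3x10^7 loci, 1/8 of
#' them QTL-class), mutation rate 4e-6, and 4 IBD tracer loci per cM
#' (12,024 loci).
#'
#' @param nChromosomes number of chromosomes.
#' @param chromLengthCM chromosome length(s) in cM; recycled to
#'   `nChromosomes`.
#' @param lociPerCM candidate-locus density per cM.
#' @param qtlFraction fraction of candidate loci of QTL class.
#' @param mutationRate per-locus per-gamete mutation probability.
#' @param ibdLociPerCM IBD tracer locus density per cM.
#' @return A [GenomeSpec-class] object.
#' @examples
#' gs <- genomeSpec()
#' genomeLengthMorgans(gs)  # 30.06
#' nIbdLoci(gs)             # 12024
#' @export
genomeSpec <- function(nChromosomes = 18L, chromLengthCM = 167,
                       lociPerCM = 1e4, qtlFraction = 1 / 8,
                       mutationRate = 4e-6, ibdLociPerCM = 4) {
  new("GenomeSpec",
      nChromosomes = as.integer(nChromosomes),
      chromLengthCM = rep_len(as.numeric(chromLengthCM),
                              as.integer(nChromosomes)),
      lociPerCM = as.numeric(lociPerCM),
      qtlFraction = as.numeric(qtlFraction),
      mutationRate = as.numeric(mutationRate),
      ibdLociPerCM = as.numeric(ibdLociPerCM))
}

#' Reduced-scale genome preset
#'
#' A down-scaled genome for desk-scale experiments: 2 chromosomes x 100 cM,
#' 100 candidate loci/cM, mutation rate 4e-5, 1 IBD locus/cM. Structural
#' ratios (QTL fraction, equidistant maps) match the full-scale genome.
#'
#' @return A [GenomeSpec-class] object.
#' @export
reducedGenome <- function() {
  genomeSpec(nChromosomes = 2L, chromLengthCM = 100, lociPerCM = 100,
             qtlFraction = 1 / 8, mutationRate = 4e-5, ibdLociPerCM = 1)
}

#' @describeIn genomeSpec Total genome length in cM.
#' @param spec a [GenomeSpec-class].
#' @export
genomeLengthCM <- function(spec) sum(spec@chromLengthCM)

#' @describeIn genomeSpec Total genome length in Morgans (the expected
#'   crossover count per meiosis).
#' @export
genomeLengthMorgans <- function(spec) genomeLengthCM(spec) / 100

#' @describeIn genomeSpec Number of candidate loci per chromosome.
#' @export
lociPerChrom <- function(spec) as.integer(round(spec@chromLengthCM * spec@lociPerCM))

#' @describeIn genomeSpec Total number of candidate loci.
#' @export
nLoci <- function(spec) sum(lociPerChrom(spec))

#' @describeIn genomeSpec Expected number of QTL-class candidate loci.
#' @export
nQtlClassLoci <- function(spec) round(nLoci(spec) * spec@qtlFraction)

#' @describeIn genomeSpec Number of IBD tracer loci.
#' @export
nIbdLoci <- function(spec) as.integer(round(sum(spec@chromLengthCM * spec@ibdLociPerCM)))

## cumulative locus-count offsets, one per chromosome (0-based)
chromLocusOffsets <- function(spec) c(0L, cumsum(lociPerChrom(spec)))

## chromosome index for genome-wide locus ids
locusChrom <- function(spec, locus) {
  findInterval(locus - 0.5, chromLocusOffsets(spec))
}

## genetic position (cM, within chromosome) for genome-wide locus ids
locusPosCM <- function(spec, locus) {
  off <- chromLocusOffsets(spec)
  chr <- locusChrom(spec, locus)
  (locus - off[chr] - 0.5) / spec@lociPerCM
}

## IBD tracer positions: midpoints of a uniform 1/ibdLociPerCM cM grid
ibdMap <- function(spec) {
  perChrom <- as.integer(round(spec@chromLengthCM * spec@ibdLociPerCM))
  chr <- rep.int(seq_len(spec@nChromosomes), perChrom)
  pos <- unlist(lapply(seq_len(spec@nChromosomes), function(c) {
    (seq_len(perChrom[c]) - 0.5) / spec@ibdLociPerCM
  }), use.names = FALSE)
  data.frame(chrom = chr, posCM = pos)
}

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec:", object@nChromosomes, "chromosomes,",
      genomeLengthCM(object), "cM (", genomeLengthMorgans(object), "Morgans)\n")
  cat("  candidate loci:", nLoci(object),
      sprintf("(%.3g QTL-class, fraction %.4g)", nQtlClassLoci(object),
              object@qtlFraction), "\n")
  cat("  mutation rate:", object@mutationRate, "per locus per gamete\n")
  cat("  IBD tracer loci:", nIbdLoci(object), "\n")
})

#' Narrow-sense heritability implied by variance components
#'
#' @param sigmaG2 additive-genetic variance.
#' @param sigmaE2 residual variance.
#' @return `sigmaG2 / (sigmaG2 + sigmaE2)`.
#' @examples
#' heritability(1, 4)  # 0.2
#' @export
heritability <- function(sigmaG2, sigmaE2) sigmaG2 / (sigmaG2 + sigmaE2)
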