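#' @include trait.R
NULL

#' Breeding population with dense genotypes and IBD tracer labels
#'
#' Holds every animal ever produced in a breeding scheme: a pedigree table
#' and, per animal, two haplotype rows over the segregating loci carried
#' into the scheme (0/1 derived-allele indicators) plus two rows of integer
#' IBD tracer labels. Base animals carry 2n distinct labels at every IBD
#' locus, so identical labels in any later generation indicate identity by
#' descent relative to the base.
#'
#' @slot spec the [GenomeSpec-class].
#' @slot loci data.frame of scheme loci: `locus`, `chrom`, `posCM`, `class`,
#'   `baseFreq` (derived-allele frequency among base animals, frozen).
#' @slot H1,H2 integer matrices (animals x loci), paternal/maternal 0/1.
#' @slot ibd data.frame of IBD loci: `chrom`, `posCM`.
#' @slot I1,I2 integer matrices (animals x IBD loci) of base-allele labels.
#' @slot ped data.frame: `id`, `sire`, `dam` (0 = base/unknown), `sex`
#'   ("M"/"F"), `gen`, `tbv`, `phen` (NA until phenotyped).
#' @export
setClass("BreedingPop", representation(
  spec = "GenomeSpec", loci = "data.frame",
  H1 = "matrix", H2 = "matrix",
  ibd = "data.frame", I1 = "matrix", I2 = "matrix",
  ped = "data.frame"))

setValidity("BreedingPop", function(object) {
  n <- nrow(object@ped)
  msg <- character()
  if (nrow(object@H1) != n || nrow(object@H2) != n ||
      nrow(object@I1) != n || nrow(object@I2) != n)
    msg <- c(msg, "haplotype/IBD row counts must match the pedigree")
  if (ncol(object@H1) != nrow(object@loci))
    msg <- c(msg, "haplotype columns must match the loci table")
  if (ncol(object@I1) != nrow(object@ibd))
    msg <- c(msg, "IBD columns must match the IBD map")
  base <- object@ped$gen == 0L
  if (any(object@ped$sire[base] != 0L) || any(object@ped$dam[base] != 0L))
    msg <- c(msg, "base animals must have unknown parents")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BreedingPop", function(object) {
  cat("BreedingPop:", nrow(object@ped), "animals over generations",
      min(object@ped$gen), "-", max(object@ped$gen), ";",
      nrow(object@loci), "loci,", nrow(object@ibd), "IBD tracer loci\n")
})

#' @describeIn BreedingPop-class Number of animals.
#' @param pop a [BreedingPop-class].
#' @export
nAnimals <- function(pop) nrow(pop@ped)

#' @describeIn BreedingPop-class Pedigree table.
#' @export
pedigree <- function(pop) pop@ped

#' @describeIn BreedingPop-class Scheme loci table (with base frequencies).
#' @export
schemeLoci <- function(pop) pop@loci

#' @describeIn BreedingPop-class Dosage matrix (0/1/2) for given animals and
#'   locus ids.
#' @param ids animal ids (default all).
#' @param lociIds genome-wide locus ids (default all scheme loci).
#' @export
dosageMatrix <- function(pop, ids = pop@ped$id,
                         lociIds = pop@loci$locus) {
  rows <- match(ids, pop@ped$id)
  cols <- match(lociIds, pop@loci$locus)
  if (anyNA(rows)) stop("unknown animal id")
  if (anyNA(cols)) stop("unknown locus id")
  d <- pop@H1[rows, cols, drop = FALSE] + pop@H2[rows, cols, drop = FALSE]
  rownames(d) <- as.character(ids)
  colnames(d) <- as.character(lociIds)
  d
}

#' Sample the base population from founder chromosome pools
#'
#' For each base animal and each chromosome, two haplotypes are drawn
#' without replacement from that chromosome's pool of 2N founder
#' haplotypes; the pool is restored before the next animal, and chromosomes
#' combine independently across pools. Genotypes are densified over the
#' segregating loci; IBD tracer loci receive 2n distinct labels
#' (animal i: labels 2i-1 and 2i at every locus). Base-population
#' derived-allele frequencies are computed and frozen in the loci table.
#'
#' @param pools a [FounderPools-class].
#' @param trait a [TraitModel-class]; QTL-class loci not in the trait model
#'   are excluded from the scheme loci.
#' @param nMales,nFemales base sex counts (paper scale 10 and 100).
#' @return A [BreedingPop-class] of generation-0 animals (genotyped, not
#'   phenotyped).
#' @export
sampleBase <- function(pools, trait, nMales = 10L, nFemales = 100L) {
  spec <- pools@spec
  loci <- segregatingLoci(pools)
  keep <- loci$class == "marker" | loci$locus %in% trait@qtlLocus
  loci <- loci[keep, c("locus", "chrom", "posCM", "class")]
  n <- as.integer(nMales + nFemales)
  nHap <- length(pools@haps)
  if (nHap < 2L) stop("founder pools must hold at least 2 haplotypes")

  hapMat <- founderHapMatrix(pools, loci$locus)   # 2N x loci, 0/1
  chromCols <- split(seq_len(nrow(loci)), loci$chrom)

  H1 <- matrix(0L, n, nrow(loci))
  H2 <- matrix(0L, n, nrow(loci))
  for (i in seq_len(n)) {
    for (c in seq_len(spec@nChromosomes)) {
      pick <- sample.int(nHap, 2L)                # without replacement
      cols <- chromCols[[as.character(c)]]
      if (!is.null(cols)) {
        H1[i, cols] <- hapMat[pick[1L], cols]
        H2[i, cols] <- hapMat[pick[2L], cols]
      }
    }
  }

  imap <- ibdMap(spec)
  I1 <- matrix(rep(2L * seq_len(n) - 1L, nrow(imap)), n, nrow(imap))
  I2 <- matrix(rep(2L * seq_len(n), nrow(imap)), n, nrow(imap))

  loci$baseFreq <- colMeans(H1 + H2) / 2
  qcols <- match(trait@qtlLocus, loci$locus)
  tbv <- computeTbv(H1[, qcols, drop = FALSE] + H2[, qcols, drop = FALSE],
                    trait)
  ped <- data.frame(
    id = seq_len(n), sire = 0L, dam = 0L,
    sex = rep(c("M", "F"), c(nMales, nFemales)),
    gen = 0L, tbv = tbv, phen = NA_real_,
    stringsAsFactors = FALSE)
  new("BreedingPop", spec = spec, loci = loci, H1 = H1, H2 = H2,
      ibd = imap, I1 = I1, I2 = I2, ped = ped)
}

## produce offspring rows from a mating list; one recombination pattern per
## gamete drives both the segregating loci and the IBD tracer loci
produceOffspring <- function(pop, matings, trait, generation, sexes) {
  nOff <- nrow(matings)
  nL <- nrow(pop@loci)
  nI <- nrow(pop@ibd)
  H1 <- matrix(0L, nOff, nL); H2 <- matrix(0L, nOff, nL)
  I1 <- matrix(0L, nOff, nI); I2 <- matrix(0L, nOff, nI)
  sRow <- match(matings$sire, pop@ped$id)
  dRow <- match(matings$dam, pop@ped$id)
  for (k in seq_len(nOff)) {
    pat <- sampleRecombination(pop@spec)
    src <- recombSource(pat, pop@loci$chrom, pop@loci$posCM)
    srcI <- recombSource(pat, pop@ibd$chrom, pop@ibd$posCM)
    H1[k, ] <- applyRecombDense(src, pop@H1[sRow[k], ], pop@H2[sRow[k], ])
    I1[k, ] <- applyRecombDense(srcI, pop@I1[sRow[k], ], pop@I2[sRow[k], ])
    pat <- sampleRecombination(pop@spec)
    src <- recombSource(pat, pop@loci$chrom, pop@loci$posCM)
    srcI <- recombSource(pat, pop@ibd$chrom, pop@ibd$posCM)
    H2[k, ] <- applyRecombDense(src, pop@H1[dRow[k], ], pop@H2[dRow[k], ])
    I2[k, ] <- applyRecombDense(srcI, pop@I1[dRow[k], ], pop@I2[dRow[k], ])
  }
  qcols <- match(trait@qtlLocus, pop@loci$locus)
  tbv <- computeTbv(H1[, qcols, drop = FALSE] + H2[, qcols, drop = FALSE],
                    trait)
  phen <- simulatePhenotype(tbv, trait@sigmaE2)
  ids <- max(pop@ped$id) + seq_len(nOff)
  ped <- data.frame(id = ids, sire = matings$sire, dam = matings$dam,
                    sex = sexes, gen = as.integer(generation),
                    tbv = tbv, phen = phen, stringsAsFactors = FALSE)
  new("BreedingPop", spec = pop@spec, loci = pop@loci,
      H1 = rbind(pop@H1, H1), H2 = rbind(pop@H2, H2),
      ibd = pop@ibd, I1 = rbind(pop@I1, I1), I2 = rbind(pop@I2, I2),
      ped = rbind(pop@ped, ped))
}
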