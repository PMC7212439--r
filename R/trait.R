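#' @include founder.R
NULL

#' Trait model: QTL identities and standardized additive effects
#'
#' The trait is fully additive: TBV_i = sum_j x_ij g_j over the trait QTL,
#' with x_ij the mutant-allele dosage. Effects are standardized by a single
#' scalar so that the (population, divide-by-n) variance of TBV over the
#' reference animals -- the founder generation-0 animals -- equals 1.
#'
#' @slot qtlLocus integer genome-wide locus ids of the trait QTL.
#' @slot effect standardized additive effect of the mutant allele per QTL.
#' @slot scale the scalar applied to the raw effects.
#' @slot sigmaG2 additive-genetic variance in the reference animals (1 by
#'   construction).
#' @slot sigmaE2 residual (environmental) variance of the phenotype.
#' @export
setClass("TraitModel", representation(
  qtlLocus = "integer", effect = "numeric", scale = "numeric",
  sigmaG2 = "numeric", sigmaE2 = "numeric"))

setValidity("TraitModel", function(object) {
  if (length(object@qtlLocus) != length(object@effect))
    return("one effect per QTL locus required")
  if (object@sigmaE2 <= 0) return("sigmaE2 must be positive")
  TRUE
})

setMethod("show", "TraitModel", function(object) {
  cat("TraitModel:", length(object@qtlLocus), "QTL, sigma_g^2 =",
      object@sigmaG2, ", sigma_e^2 =", object@sigmaE2,
      sprintf("(h2 = %.3g)\n",
              heritability(object@sigmaG2, object@sigmaE2)))
})

#' True breeding values from dosages and effects
#'
#' @param dosage animals x QTL dosage matrix (0/1/2), columns in the order
#'   of `trait@qtlLocus`.
#' @param trait a [TraitModel-class] (or a bare numeric effect vector).
#' @return numeric vector of TBVs.
#' @export
computeTbv <- function(dosage, trait) {
  eff <- if (is(trait, "TraitModel")) trait@effect else trait
  as.vector(dosage %*% eff)
}

#' Standardize QTL effects to unit additive variance
#'
#' Scales all raw effects by one scalar so the population variance
#' (divide by n) of TBV over the reference animals equals 1.
#'
#' @param rawEffect numeric raw effects.
#' @param refDosage reference animals x QTL dosage matrix.
#' @return list with `effect` (standardized), `scale`.
#' @export
standardizeEffects <- function(rawEffect, refDosage) {
  tbv <- as.vector(refDosage %*% rawEffect)
  v <- mean((tbv - mean(tbv))^2)
  if (v <= 0)
    stop("zero additive variance before scaling: no segregating QTL with effect")
  s <- 1 / sqrt(v)
  list(effect = rawEffect * s, scale = s)
}

#' Build the trait model from founder pools
#'
#' Selects the trait QTL (all segregating QTL-class loci, or a uniform
#' random subset of `nQtl` of them) and standardizes their effects so the
#' founder generation-0 animals have additive variance 1. QTL removed by
#' subsampling cease to exist for the trait and are excluded from all
#' downstream relationship matrices.
#'
#' @param pools a [FounderPools-class].
#' @param nQtl `"all"` or the number of QTL to retain by random subsampling.
#' @param sigmaE2 residual variance of the phenotype (default 4, giving
#'   h2 = 0.2 with unit additive variance).
#' @return A [TraitModel-class].
#' @export
makeTraitModel <- function(pools, nQtl = "all", sigmaE2 = 4) {
  loci <- segregatingLoci(pools)
  qtl <- loci[loci$class == "qtl", , drop = FALSE]
  if (!nrow(qtl)) stop("no segregating QTL in the founder pools")
  if (!identical(nQtl, "all")) {
    nQtl <- as.integer(nQtl)
    if (nQtl > nrow(qtl))
      stop("requested ", nQtl, " QTL but only ", nrow(qtl), " segregate")
    keep <- sort(sample.int(nrow(qtl), nQtl))
    qtl <- qtl[keep, , drop = FALSE]
  }
  ref <- founderDosage(pools, qtl$locus)
  st <- standardizeEffects(qtl$rawEffect, ref)
  new("TraitModel", qtlLocus = as.integer(qtl$locus), effect = st$effect,
      scale = st$scale, sigmaG2 = 1, sigmaE2 = as.numeric(sigmaE2))
}

#' Simulate phenotypes
#'
#' P_i = TBV_i + e_i with e_i ~ N(0, sigmaE2).
#'
#' @param tbv numeric vector of true breeding values.
#' @param sigmaE2 residual variance.
#' @return numeric vector of phenotypes.
#' @export
simulatePhenotype <- function(tbv, sigmaE2) {
  if (sigmaE2 < 0) stop("sigmaE2 must be non-negative")
  if (sigmaE2 == 0) return(tbv)
  tbv + rnorm(length(tbv), 0, sqrt(sigmaE2))
}
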