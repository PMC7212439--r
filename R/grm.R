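#' @include population.R
NULL

#' Genomic relationship matrix (VanRaden method 2)
#'
#' G = W D^-1 W' / L, where W holds dosages centered by twice the
#' base-population derived-allele frequency, D_ii = 2 p_i (1 - p_i), and L
#' is the number of loci used. Base frequencies are computed once from the
#' base population and frozen; loci monomorphic in the base (p in {0,1})
#' are excluded. The scaled genotypes are retained so the matrix can be
#' extended as new animals are genotyped.
#'
#' Centering and scaling are invariant to which allele is labelled minor;
#' the derived-allele frequency is used throughout.
#'
#' @slot values symmetric relationship matrix with animal-id dimnames.
#' @slot animalIds character vector, the animal order.
#' @slot source one of "M" (markers), "Q" (trait QTL), "A" (both).
#' @slot baseFreq base derived-allele frequencies of the loci used.
#' @slot lociId genome-wide ids of the loci used.
#' @slot scaledGeno W D^-1/2 / sqrt(L): G = scaledGeno %*% t(scaledGeno).
#' @export
setClass("RelationshipMatrix", representation(
  values = "matrix", animalIds = "character", source = "character",
  baseFreq = "numeric", lociId = "integer", scaledGeno = "matrix"))

setValidity("RelationshipMatrix", function(object) {
  msg <- character()
  n <- length(object@animalIds)
  if (!all(dim(object@values) == n))
    msg <- c(msg, "values must be square over the animal order")
  if (n && max(abs(object@values - t(object@values))) > 1e-12)
    msg <- c(msg, "values must be symmetric within 1e-12")
  if (!object@source %in% c("M", "Q", "A"))
    msg <- c(msg, "source must be one of M, Q, A")
  if (length(object@baseFreq) != length(object@lociId))
    msg <- c(msg, "one base frequency per locus used")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix (G_", object@source, "): ",
      length(object@animalIds), " animals, ", length(object@lociId),
      " loci\n", sep = "")
  if (length(object@animalIds))
    cat("  mean diagonal:", round(mean(diag(object@values)), 4), "\n")
})

#' @describeIn RelationshipMatrix-class The relationship matrix values.
#' @param g a [RelationshipMatrix-class].
#' @export
grmValues <- function(g) g@values

#' @describeIn RelationshipMatrix-class Animal order.
#' @export
grmAnimals <- function(g) g@animalIds

#' @describeIn RelationshipMatrix-class Number of loci used (after the
#'   base-frequency filter).
#' @export
nLociUsed <- function(g) length(g@lociId)

## internal: center and scale a dosage block
scaleGeno <- function(geno, baseFreq, L) {
  W <- sweep(geno, 2L, 2 * baseFreq)
  sweep(W, 2L, sqrt(2 * baseFreq * (1 - baseFreq) * L), "/")
}

#' Compute a genomic relationship matrix
#'
#' @param geno animals x loci dosage matrix with entries in 0/1/2 and
#'   animal-id rownames.
#' @param baseFreq per-locus derived-allele frequency in the base
#'   population (frozen for the whole scheme).
#' @param source locus-class tag: "M", "Q", or "A".
#' @param lociId genome-wide locus ids (default: column index).
#' @return A [RelationshipMatrix-class].
#' @export
computeGrm <- function(geno, baseFreq, source = "M",
                       lociId = seq_len(ncol(geno))) {
  geno <- as.matrix(geno)
  if (length(baseFreq) != ncol(geno))
    stop("one base frequency per locus required")
  if (any(!geno %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, or 2")
  keep <- baseFreq > 0 & baseFreq < 1
  if (!any(keep))
    stop("all loci are monomorphic in the base population")
  geno <- geno[, keep, drop = FALSE]
  p <- baseFreq[keep]
  L <- sum(keep)
  S <- scaleGeno(geno, p, L)
  G <- tcrossprod(S)
  G <- (G + t(G)) / 2
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(geno)))
  dimnames(G) <- list(ids, ids)
  new("RelationshipMatrix", values = G, animalIds = ids,
      source = source, baseFreq = p,
      lociId = as.integer(lociId[keep]), scaledGeno = S)
}

#' Extend a relationship matrix with newly genotyped animals
#'
#' Identical (within numerical tolerance) to recomputing [computeGrm()] on
#' the concatenated genotype matrix; the stored base frequencies and locus
#' set are reused.
#'
#' @param g a [RelationshipMatrix-class].
#' @param geno new animals x loci dosage matrix over the same locus set
#'   (before the base-frequency filter), with animal-id rownames.
#' @param lociId locus ids of `geno`'s columns (default: assume the same
#'   pre-filter order used to build `g`, given by attribute or length).
#' @return The extended [RelationshipMatrix-class].
#' @export
extendGrm <- function(g, geno, lociId = NULL) {
  geno <- as.matrix(geno)
  if (!is.null(lociId)) {
    cols <- match(g@lociId, lociId)
    if (anyNA(cols)) stop("locus mismatch between matrix and new genotypes")
    geno <- geno[, cols, drop = FALSE]
  } else if (ncol(geno) != length(g@lociId)) {
    stop("new genotypes must cover the matrix's locus set")
  }
  if (nrow(geno) == 0L) return(g)
  if (any(!geno %in% c(0, 1, 2))) stop("dosages must be 0, 1, or 2")
  L <- length(g@lociId)
  S2 <- scaleGeno(geno, g@baseFreq, L)
  cross <- g@scaledGeno %*% t(S2)
  G22 <- tcrossprod(S2)
  vals <- rbind(cbind(g@values, cross), cbind(t(cross), (G22 + t(G22)) / 2))
  ids2 <- rownames(geno)
  if (is.null(ids2)) ids2 <- as.character(length(g@animalIds) + seq_len(nrow(geno)))
  ids <- c(g@animalIds, ids2)
  dimnames(vals) <- list(ids, ids)
  new("RelationshipMatrix", values = vals, animalIds = ids,
      source = g@source, baseFreq = g@baseFreq, lociId = g@lociId,
      scaledGeno = rbind(g@scaledGeno, S2))
}

#' Select loci by relationship-matrix source
#'
#' "M" selects marker-class loci, "Q" the trait QTL currently in the trait
#' model, "A" their union; ordering is deterministic by (chromosome,
#' position), i.e. by genome-wide locus id.
#'
#' @param loci a scheme loci table (see [schemeLoci()]).
#' @param source "M", "Q", or "A".
#' @param traitQtl integer locus ids of the trait QTL.
#' @return sorted integer vector of genome-wide locus ids.
#' @export
selectLoci <- function(loci, source, traitQtl) {
  ids <- switch(source,
    M = loci$locus[loci$class == "marker"],
    Q = intersect(loci$locus, traitQtl),
    A = loci$locus[loci$class == "marker" | loci$locus %in% traitQtl],
    stop("source must be one of M, Q, A"))
  ids <- sort(as.integer(ids))
  if (!length(ids)) stop("empty locus selection for source ", source)
  ids
}

#' Build a relationship matrix for a breeding population
#'
#' @param pop a [BreedingPop-class] (base frequencies are taken from its
#'   loci table).
#' @param source "M", "Q", or "A".
#' @param traitQtl trait QTL locus ids (required for "Q" and "A").
#' @param ids animals to include (default all).
#' @return A [RelationshipMatrix-class].
#' @export
buildGrm <- function(pop, source, traitQtl, ids = pop@ped$id) {
  lociIds <- selectLoci(pop@loci, source, traitQtl)
  rows <- match(lociIds, pop@loci$locus)
  geno <- dosageMatrix(pop, ids, lociIds)
  computeGrm(geno, pop@loci$baseFreq[rows], source = source,
             lociId = lociIds)
}
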