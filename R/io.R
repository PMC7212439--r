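#' @include population.R
NULL

## Plain-text exports of the package's central objects. All formats are
## whitespace-delimited text so runs can be archived and inspected with
## standard tools.

#' Write a locus map
#'
#' Tab-delimited: locus id, chromosome, position (cM), class, base
#' frequency, (standardized) effect for trait QTL.
#'
#' @param loci a loci table ([segregatingLoci()] or [schemeLoci()]).
#' @param file output path.
#' @param trait optional [TraitModel-class] to annotate effects.
#' @export
writeLocusMap <- function(loci, file, trait = NULL) {
  out <- loci
  if (!is.null(trait)) {
    out$effect <- 0
    hit <- match(trait@qtlLocus, out$locus)
    out$effect[hit[!is.na(hit)]] <- trait@effect[!is.na(hit)]
  }
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a pedigree as a 3-column text file
#'
#' Columns id, sire, dam with 0 for unknown parents, compatible with
#' common pedigree tools.
#'
#' @param pop a [BreedingPop-class] (or a pedigree data.frame).
#' @param file output path.
#' @export
writePedigree <- function(pop, file) {
  ped <- if (is(pop, "BreedingPop")) pedigree(pop) else pop
  write.table(ped[, c("id", "sire", "dam")], file, sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Write a dosage matrix as tab-delimited text
#'
#' Animals in rows (id column first), loci in columns (0/1/2 dosages).
#'
#' @param pop a [BreedingPop-class].
#' @param file output path.
#' @param ids,lociIds subset selectors (defaults: all).
#' @export
writeDosage <- function(pop, file, ids = pop@ped$id,
                        lociIds = pop@loci$locus) {
  d <- dosageMatrix(pop, ids, lociIds)
  out <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a relationship matrix as lower-triangle text
#'
#' Rows: row-id, col-id, value, for the lower triangle including the
#' diagonal; the locus list used is written alongside as `<file>.loci`.
#'
#' @param g a [RelationshipMatrix-class].
#' @param file output path.
#' @export
writeGrmText <- function(g, file) {
  v <- grmValues(g)
  idx <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(row = grmAnimals(g)[idx[, 1L]],
                    col = grmAnimals(g)[idx[, 2L]],
                    value = v[idx])
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.character(g@lociId), paste0(file, ".loci"))
}

#' Write phased genotypes as a minimal VCF
#'
#' Biallelic sites with phased GT fields; positions are the genetic-map
#' positions scaled to integer base pairs (1 cM = 1e6 bp). REF/ALT are
#' placeholder A/B alleles (the simulation has no nucleotide sequence).
#'
#' @param pop a [BreedingPop-class].
#' @param file output path.
#' @param ids animals to include (default all).
#' @export
writeVcf <- function(pop, file, ids = pop@ped$id) {
  rows <- match(ids, pop@ped$id)
  loci <- pop@loci
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=gocsim",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       paste0("ind", ids)), collapse = "\t")), con)
  gt <- matrix(paste0(t(pop@H1[rows, , drop = FALSE]), "|",
                      t(pop@H2[rows, , drop = FALSE])),
               nrow = nrow(loci))
  body <- cbind(loci$chrom, as.integer(round(loci$posCM * 1e6)),
                paste0("L", loci$locus), "A", "B", ".", "PASS", ".", "GT",
                gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
}

#' Write a GEBV table
#'
#' Tab-delimited: animal id, generation, sex, gebv, phenotype-present flag.
#'
#' @param fit a [GblupFit-class].
#' @param pop a [BreedingPop-class].
#' @param file output path.
#' @export
writeGebvTable <- function(fit, pop, file) {
  ped <- pedigree(pop)
  g <- gebv(fit)[as.character(ped$id)]
  out <- data.frame(id = ped$id, generation = ped$gen, sex = ped$sex,
                    gebv = unname(g), hasPhenotype = !is.na(ped$phen))
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a mating plan
#'
#' Tab-delimited: mating index, sire id, dam id, offspring per mating.
#'
#' @param plan a data.frame from [matingPlan()].
#' @param offspringPerMating offspring produced per mating.
#' @param file output path.
#' @export
writeMatingPlan <- function(plan, offspringPerMating, file) {
  plan$nOffspring <- offspringPerMating
  write.table(plan, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Serialize founder pools to plain text
#'
#' Two files: `<file>.loci` (the segregating-locus map with raw effects)
#' and `<file>.haps` (one line per haplotype: space-separated derived-
#' allele locus ids). [readFounderPools()] restores the object.
#'
#' @param pools a [FounderPools-class].
#' @param file path stem.
#' @export
writeFounderPools <- function(pools, file) {
  write.table(segregatingLoci(pools), paste0(file, ".loci"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(vapply(pools@haps, function(h)
    paste(h, collapse = " "), character(1)), paste0(file, ".haps"))
}

#' @describeIn writeFounderPools Restore founder pools written by
#'   [writeFounderPools()] (the genome spec must be supplied).
#' @param spec the [GenomeSpec-class] the pools were simulated under.
#' @export
readFounderPools <- function(file, spec) {
  loci <- read.table(paste0(file, ".loci"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  haps <- lapply(strsplit(readLines(paste0(file, ".haps")), " "),
                 function(x) as.integer(x[nzchar(x)]))
  new("FounderPools", spec = spec, haps = haps, loci = loci,
      popSize = as.integer(length(haps) / 2L))
}
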