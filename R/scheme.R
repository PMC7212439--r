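#' @include population.R
#' @include ocs.R
#' @include gblup.R
#' @include metrics.R
NULL

#' Breeding-scheme configuration
#'
#' Defaults reproduce the full-scale study scheme: a base population of 10
#' males and 100 females; generation 1 by random mating (each base dam
#' mated once to a uniformly drawn base sire, 5 offspring each, exact equal
#' sex ratio); truncation selection on GEBV in generations 2-5 (10 sires x
#' 10 dams each x 5 offspring, exact equal sex ratio); optimum-contribution
#' selection in generations 6-11 (25 matings among the ~500 current-
#' generation candidates, 20 offspring per mating, offspring sex Bernoulli
#' 0.5). Variance components are sigma_g^2 = 1, sigma_e^2 = 4 (h^2 = 0.2).
#'
#' @param predSource relationship matrix for GEBV prediction: "M", "Q", "A".
#' @param coanSource relationship matrix for coancestry control: "M", "A".
#' @param truncPredSource relationship matrix driving truncation-phase
#'   GEBVs; default `NULL` uses `predSource`. Setting a common source
#'   (e.g. "M") across scenarios makes the pre-OCS history identical under
#'   paired seeds, so scenarios differ only in the OCS phase.
#' @param nQtl trait architecture: "all" or a QTL count.
#' @param penalty coancestry penalty weight w >= 0 (a printed penalty of
#'   -50 corresponds to w = 50).
#' @param nGen last generation born.
#' @param truncGens,ocsGens generation spans of the two selection phases.
#' @param baseMales,baseFemales base population sex counts.
#' @param gen1OffPerDam offspring per base dam in generation 1.
#' @param truncSires,truncDams,truncOffPerMating truncation-phase structure
#'   (`truncDams` must be a multiple of `truncSires`).
#' @param nMatings,offPerMating OCS-phase structure.
#' @param sigmaG2,sigmaE2 variance components used in G-BLUP.
#' @param selection "gocs" for the full scheme, or "random" for a
#'   random-selection control (no GEBV, no coancestry control) used to
#'   verify the transmission machinery against classical expectations.
#' @param randomSires,randomDams,randomOffPerMating structure of the
#'   random-selection control (equal contributions, each dam mated once).
#' @param eaBudget,eaPopSize evolutionary-search effort per OCS round.
#' @return a list of class-checked settings.
#' @export
schemeConfig <- function(predSource = "Q", coanSource = "M",
                         truncPredSource = NULL,
                         nQtl = "all", penalty = 25,
                         nGen = 11L, truncGens = 2:5, ocsGens = 6:11,
                         baseMales = 10L, baseFemales = 100L,
                         gen1OffPerDam = 5L,
                         truncSires = 10L, truncDams = 100L,
                         truncOffPerMating = 5L,
                         nMatings = 25L, offPerMating = 20L,
                         sigmaG2 = 1, sigmaE2 = 4,
                         selection = c("gocs", "random"),
                         randomSires = 25L, randomDams = 25L,
                         randomOffPerMating = 20L,
                         eaBudget = 1500L, eaPopSize = 24L) {
  selection <- match.arg(selection)
  stopifnot(predSource %in% c("M", "Q", "A"), coanSource %in% c("M", "A"),
            truncDams %% truncSires == 0L, penalty >= 0)
  as.list(environment())
}

#' Reduced-scale scheme preset
#'
#' The desk-scale counterpart of [schemeConfig()], sized for the
#' [reducedGenome()]: base 10 males + 50 females, 150 offspring per
#' generation (generation 1: 3 per dam; truncation: 10 sires x 3 dams x 5
#' offspring; OCS: 15 matings x 10 offspring), preserving the full-scale
#' structural ratios.
#'
#' @param ... overrides passed to [schemeConfig()].
#' @export
reducedSchemeConfig <- function(...) {
  args <- list(baseFemales = 50L, gen1OffPerDam = 3L,
               truncDams = 30L, truncOffPerMating = 5L,
               nMatings = 15L, offPerMating = 10L,
               randomOffPerMating = 6L)
  over <- list(...)
  args[names(over)] <- over
  do.call(schemeConfig, args)
}

#' Scheme replicate result
#'
#' @slot records per-generation data.frame: `gen`, `n`, `meanTbv`,
#'   `meanFtrue`, `meanFped`, `objective` (NA outside the OCS phase).
#' @slot dG rate of genetic gain over the OCS span.
#' @slot dFtrue,dFped rates of true and pedigree inbreeding over the span.
#' @slot accMale,accFemale final-generation prediction accuracy by sex
#'   (NA for the random-selection control).
#' @slot penalty the penalty weight used.
#' @slot pop the final [BreedingPop-class].
#' @slot config the configuration list.
#' @export
setClass("SchemeResult", representation(
  records = "data.frame", dG = "numeric", dFtrue = "numeric",
  dFped = "numeric", accMale = "numeric", accFemale = "numeric",
  penalty = "numeric", pop = "BreedingPop", config = "list"))

setMethod("show", "SchemeResult", function(object) {
  cat("SchemeResult:", nrow(object@records), "generations;",
      sprintf("dG = %.3f, dF_true = %.4f, dF_ped = %.4f\n",
              object@dG, object@dFtrue, object@dFped))
  if (is.finite(object@accMale))
    cat(sprintf("  final accuracy: males %.3f, females %.3f\n",
                object@accMale, object@accFemale))
})

#' @describeIn SchemeResult-class Per-generation records.
#' @param x a [SchemeResult-class].
#' @export
generationRecords <- function(x) x@records

## deterministic keyed sub-seed derivation (31-bit)
deriveSeed <- function(master, key) {
  as.integer((as.numeric(master) * 48271 + as.numeric(key) * 16807 + 1) %%
             2147483647)
}

#' Run one breeding-scheme replicate
#'
#' Samples a unique base population from the founder pools, runs random
#' mating (generation 1), truncation selection on GEBV (the truncation
#' span), and optimum-contribution selection (the OCS span), then computes
#' rates of gain and inbreeding over the OCS span and final-generation
#' prediction accuracies.
#'
#' @param pools a [FounderPools-class] (shared across replicates).
#' @param config a [schemeConfig()] list.
#' @param seed integer master seed for this replicate; all streams (trait
#'   subsampling, base sampling, scheme events) derive from it.
#' @return A [SchemeResult-class].
#' @export
runScheme <- function(pools, config, seed) {
  set.seed(deriveSeed(seed, 1L))
  trait <- makeTraitModel(pools, config$nQtl, config$sigmaE2)
  set.seed(deriveSeed(seed, 2L))
  pop <- sampleBase(pools, trait, config$baseMales, config$baseFemales)
  set.seed(deriveSeed(seed, 3L))

  gocs <- config$selection == "gocs"
  truncSrc <- if (is.null(config$truncPredSource)) config$predSource
              else config$truncPredSource
  G <- list()
  if (gocs) {
    for (s in unique(c(config$predSource, config$coanSource, truncSrc)))
      G[[s]] <- buildGrm(pop, s, trait@qtlLocus)
  }
  extendAll <- function(newIds) {
    if (!gocs) return(invisible())
    for (s in names(G))
      G[[s]] <<- extendGrm(G[[s]], dosageMatrix(pop, newIds, G[[s]]@lociId))
  }
  fitNow <- function(source) {
    ph <- pop@ped[pop@ped$gen >= 1L, ]
    fitGblup(data.frame(animal = ph$id, y = ph$phen), G[[source]],
             config$sigmaG2, config$sigmaE2)
  }

  nGen <- config$nGen
  objective <- rep(NA_real_, nGen)
  for (t in seq_len(nGen)) {
    cand <- pop@ped[pop@ped$gen == t - 1L, ]
    if (t == 1L) {
      dams <- cand$id[cand$sex == "F"]
      males <- cand$id[cand$sex == "M"]
      sires <- males[sample.int(length(males), length(dams), replace = TRUE)]
      plan <- data.frame(sire = sires, dam = dams)
      perMating <- config$gen1OffPerDam
      exactSex <- TRUE
    } else if (t %in% config$truncGens) {
      if (!gocs) {
        plan <- randomControlPlan(cand, config)   # one offspring per row
        perMating <- 1L
        exactSex <- FALSE
      } else {
        fit <- fitNow(truncSrc)
        gb <- gebv(fit)[as.character(cand$id)]
        plan <- truncationMatings(cand, gb, config)
        perMating <- config$truncOffPerMating
        exactSex <- TRUE
      }
    } else {
      if (!gocs) {
        plan <- randomControlPlan(cand, config)   # one offspring per row
        perMating <- 1L
        exactSex <- FALSE
      } else {
        fit <- fitNow(config$predSource)
        gb <- gebv(fit)[as.character(cand$id)]
        idx <- as.character(cand$id)
        prob <- ocsProblem(gb, grmValues(G[[config$coanSource]])[idx, idx],
                           cand$sex,
                           config$penalty, config$nMatings,
                           config$offPerMating)
        sol <- solveInteger(prob, budget = config$eaBudget,
                            popSize = config$eaPopSize)
        objective[t] <- sol@objective
        pl <- matingPlan(sol)
        plan <- data.frame(sire = as.integer(pl$sire),
                           dam = as.integer(pl$dam))
        perMating <- config$offPerMating
        exactSex <- FALSE
      }
    }
    matings <- plan[rep(seq_len(nrow(plan)), each = perMating), ]
    nOff <- nrow(matings)
    sexes <- if (exactSex) rep_len(c("M", "F"), nOff)
             else sample(c("M", "F"), nOff, replace = TRUE)
    before <- pop@ped$id
    pop <- produceOffspring(pop, matings, trait, t, sexes)
    extendAll(setdiff(pop@ped$id, before))
  }

  ftrue <- trueInbreeding(pop)
  fped <- pedigreeInbreeding(pop@ped)
  rec <- do.call(rbind, lapply(0:nGen, function(t) {
    sel <- pop@ped$gen == t
    data.frame(gen = t, n = sum(sel),
               meanTbv = mean(pop@ped$tbv[sel]),
               meanFtrue = mean(ftrue[sel]),
               meanFped = mean(fped[sel]),
               objective = if (t >= 1L) objective[t] else NA_real_)
  }))

  span <- config$ocsGens
  sp <- rec[rec$gen %in% span, ]
  accM <- accF <- NA_real_
  if (gocs) {
    fit <- fitNow(config$predSource)
    final <- pop@ped[pop@ped$gen == nGen, ]
    tbv <- setNames(final$tbv, as.character(final$id))
    accM <- accuracy(fit, tbv, as.character(final$id[final$sex == "M"]))
    accF <- accuracy(fit, tbv, as.character(final$id[final$sex == "F"]))
  }
  new("SchemeResult", records = rec,
      dG = rateOfGain(sp$meanTbv, sp$gen),
      dFtrue = rateOfInbreeding(sp$meanFtrue, sp$gen),
      dFped = rateOfInbreeding(sp$meanFped, sp$gen),
      accMale = accM, accFemale = accF,
      penalty = config$penalty, pop = pop, config = config)
}

## truncation phase: top sires/dams by GEBV (ties broken by id), dams
## permuted and split into equal blocks per sire
truncationMatings <- function(cand, gb, config) {
  pick <- function(sex, k) {
    sub <- cand[cand$sex == sex, ]
    if (nrow(sub) < k) stop("fewer candidates than selection counts")
    sub$id[order(-gb[as.character(sub$id)], sub$id)][seq_len(k)]
  }
  sires <- pick("M", config$truncSires)
  dams <- sample(pick("F", config$truncDams))
  data.frame(sire = rep(sires, each = config$truncDams %/% config$truncSires),
             dam = dams)
}

## random-selection control: a random-union Wright-Fisher step restricted
## to randomSires + randomDams breeding animals drawn at random from the
## candidates; every offspring draws its sire and dam uniformly (with
## replacement) from the breeding set, so family contributions are
## Poisson-like and the classical dF = 1/(8 Nm) + 1/(8 Nf) applies
randomControlPlan <- function(cand, config) {
  males <- cand$id[cand$sex == "M"]
  fems <- cand$id[cand$sex == "F"]
  if (length(males) < config$randomSires || length(fems) < config$randomDams)
    stop("fewer candidates than selection counts")
  sires <- males[sample.int(length(males), config$randomSires)]
  dams <- fems[sample.int(length(fems), config$randomDams)]
  nOff <- config$randomDams * config$randomOffPerMating
  data.frame(sire = sires[sample.int(length(sires), nOff, replace = TRUE)],
             dam = dams[sample.int(length(dams), nOff, replace = TRUE)])
}
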