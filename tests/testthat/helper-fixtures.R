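## Shared fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

## reduced-scale founder population at mutation-drift-selection equilibrium
reducedPools <- function() {
  if (is.null(.fixtures$pools)) {
    set.seed(42)
    .fixtures$pools <- runFounder(reducedGenome(), nGenerations = 200L,
                                  popSize = 50L)
  }
  .fixtures$pools
}

## random Hardy-Weinberg dosage matrix with its realized frequencies
hweGeno <- function(n, L) {
  p <- runif(L, 0.1, 0.9)
  geno <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  rownames(geno) <- paste0("a", seq_len(n))
  geno
}

## minimal synthetic founder pools: popSize animals, empty or given haplotypes
tinyPools <- function(popSize = 2L, haps = NULL,
                      loci = data.frame(locus = 1L, chrom = 1L, posCM = 0.5,
                                        class = "marker", freq = 0.5,
                                        rawEffect = 0)) {
  if (is.null(haps)) haps <- rep(list(integer()), 2L * popSize)
  new("FounderPools", spec = reducedGenome(), haps = haps,
      loci = loci, popSize = as.integer(popSize))
}

## a trait model that carries no effects (for transmission-only tests)
nullTrait <- function(qtlLocus = 1L) {
  new("TraitModel", qtlLocus = as.integer(qtlLocus),
      effect = rep(0, length(qtlLocus)), scale = 1, sigmaG2 = 1, sigmaE2 = 4)
}
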