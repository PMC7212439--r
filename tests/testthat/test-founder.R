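test_that("founder equilibrium yields a clean segregating-loci table", {
  pools <- reducedPools()
  tab <- segregatingLoci(pools)
  expect_gt(nrow(tab), 100)
  expect_true(all(tab$freq > 0 & tab$freq < 1))
  expect_true(all(tab$class %in% c("marker", "qtl")))
  expect_true(all(diff(tab$locus) > 0))              # (chrom, pos) order
  expect_true(all(tab$rawEffect[tab$class == "marker"] == 0))
  expect_true(all(tab$rawEffect[tab$class == "qtl"] != 0))
  ## haplotypes carry only valid loci; fixed loci were pruned
  cnt <- tabulate(unlist(pools@haps), nbins = nLoci(pools@spec))
  expect_true(all(cnt[tab$locus] > 0))
  expect_true(all(cnt <= 2 * pools@popSize))
  expect_lt(max(cnt[setdiff(which(cnt > 0), tab$locus)], 0),
            2 * pools@popSize)
})

test_that("zero mutation leaves no polymorphism and fails loudly", {
  spec <- genomeSpec(nChromosomes = 1L, chromLengthCM = 10, lociPerCM = 10,
                     mutationRate = 0)
  set.seed(6)
  expect_error(runFounder(spec, 3L, 10L), "segregating")
})

test_that("QTL effect sampling matches the exponential sign-mixture", {
  set.seed(7)
  e <- sampleQtlEffects(1e5)
  expect_true(all(e != 0))
  fracPos <- mean(e > 0)
  expect_lt(abs(fracPos - 0.1), 3 * sqrt(0.1 * 0.9 / 1e5))
  expect_lt(abs(mean(abs(e)) - 1), 3 / sqrt(1e5))
})

test_that("effect standardization fixes the reference variance at 1", {
  ## two animals, one QTL, dosages 0 and 2, raw effect 3:
  ## population variance of {0, 2g} is g^2, so the scalar is 1/3
  st <- standardizeEffects(3, matrix(c(0, 2), 2, 1))
  expect_equal(st$scale, 1 / 3)
  expect_equal(st$effect, 1)
  set.seed(8)
  dos <- matrix(rbinom(200, 2, 0.4), 20, 10)
  raw <- rnorm(10)
  a <- standardizeEffects(raw, dos)
  tbv <- dos %*% a$effect
  expect_equal(mean((tbv - mean(tbv))^2), 1, tolerance = 1e-10)
  b <- standardizeEffects(2 * raw, dos)          # scale invariance
  expect_equal(a$effect, b$effect)
  expect_error(standardizeEffects(0.5, matrix(1, 5, 1)), "variance")
})

test_that("trait models subsample QTL and re-standardize", {
  pools <- reducedPools()
  nQtlSeg <- sum(segregatingLoci(pools)$class == "qtl")
  set.seed(9)
  full <- makeTraitModel(pools, "all")
  expect_equal(length(full@qtlLocus), nQtlSeg)
  sub <- makeTraitModel(pools, nQtlSeg %/% 2)
  expect_equal(length(sub@qtlLocus), nQtlSeg %/% 2)
  expect_true(all(sub@qtlLocus %in% full@qtlLocus))
  ref <- founderDosage(pools, sub@qtlLocus)
  tbv <- computeTbv(ref, sub)
  expect_equal(mean((tbv - mean(tbv))^2), 1, tolerance = 1e-10)
  expect_error(makeTraitModel(pools, nQtlSeg + 1L), "only")
})

test_that("low-TBV culling raises the mean breeding value over drift", {
  spec <- genomeSpec(nChromosomes = 2L, chromLengthCM = 50, lociPerCM = 100,
                     qtlFraction = 1 / 8, mutationRate = 2e-4,
                     ibdLociPerCM = 1)
  meanTbv <- function(p) {
    q <- segregatingLoci(p)
    q <- q[q$class == "qtl", ]
    if (!nrow(q)) return(0)
    mean(as.vector(founderDosage(p, q$locus) %*% q$rawEffect))
  }
  sel <- neu <- numeric(5)
  for (r in 1:5) {
    set.seed(100 + r)
    sel[r] <- meanTbv(runFounder(spec, 60L, 20L, cullFraction = 0.25))
    set.seed(100 + r)
    neu[r] <- meanTbv(runFounder(spec, 60L, 20L, cullFraction = 0))
  }
  ## most effects are negative, so drift alone drags the mean far down
  expect_true(all(sel - neu > 0))
})

test_that("neutral equilibrium heterozygosity matches a single-locus oracle", {
  spec <- genomeSpec(nChromosomes = 2L, chromLengthCM = 50, lociPerCM = 100,
                     qtlFraction = 1 / 8, mutationRate = 1e-4,
                     ibdLociPerCM = 1)
  set.seed(10)
  pools <- runFounder(spec, 100L, 50L, cullFraction = 0)
  tab <- segregatingLoci(pools)
  het <- mean(2 * tab$freq * (1 - tab$freq))
  set.seed(11)
  ora <- wfOracle(nLoci(spec), 1e-4, 100L, 100L)
  ## founder loci are linked/correlated, so agreement is asserted as a
  ## factor band rather than a per-locus standard error
  expect_gt(het / ora$het, 0.5)
  expect_lt(het / ora$het, 2)
  expect_gt(nrow(tab) / ora$nSeg, 0.5)
  expect_lt(nrow(tab) / ora$nSeg, 2)
})
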