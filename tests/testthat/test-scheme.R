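test_that("true breeding values are additive in mutant-allele dosage", {
  trait <- new("TraitModel", qtlLocus = c(1L, 2L), effect = c(0.3, -0.5),
               scale = 1, sigmaG2 = 1, sigmaE2 = 4)
  expect_equal(computeTbv(matrix(0, 1, 2), trait), 0)
  expect_equal(computeTbv(matrix(c(2, 0), 1, 2), trait), 0.6)
  expect_equal(computeTbv(matrix(c(1, 2), 1, 2), trait), 0.3 - 1)
})

test_that("phenotypes add Gaussian noise of the stated variance", {
  tbv <- rnorm(10)
  expect_equal(simulatePhenotype(tbv, 0), tbv)
  set.seed(31)
  tbv <- rnorm(2e4)
  p <- simulatePhenotype(tbv, 4)
  res <- p - tbv
  expect_lt(abs(var(res) - 4), 3 * sqrt(2 * 16 / 2e4))
  fit <- lm(p ~ tbv)
  expect_lt(abs(coef(fit)[2] - 1), 3 * summary(fit)$coefficients[2, 2])
})

test_that("Mendelian sampling centers offspring on the parent average", {
  pools <- reducedPools()
  set.seed(32)
  trait <- makeTraitModel(pools, "all")
  pop <- sampleBase(pools, trait, 1L, 1L)
  off <- gocsim:::produceOffspring(
    pop, data.frame(sire = rep(1L, 1500), dam = rep(2L, 1500)),
    trait, 1L, rep("M", 1500))
  ped <- pedigree(off)
  dev <- ped$tbv[ped$gen == 1L] - mean(ped$tbv[ped$gen == 0L])
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(1500))
})

test_that("a full replicate has exact phase structure and bookkeeping", {
  pools <- reducedPools()
  cfg <- reducedSchemeConfig(predSource = "Q", coanSource = "M",
                             truncPredSource = "M", penalty = 5,
                             nGen = 7L, truncGens = 2:4, ocsGens = 5:7,
                             eaBudget = 600L)
  res <- runScheme(pools, cfg, seed = 77L)
  rec <- generationRecords(res)
  expect_equal(rec$gen, 0:7)
  expect_equal(rec$n, c(60L, rep(150L, 7)))
  ped <- pedigree(res@pop)
  ## pedigree conservation: parents exist and predate their offspring
  kids <- ped[ped$gen > 0L, ]
  expect_true(all(kids$sire %in% ped$id & kids$dam %in% ped$id))
  expect_true(all(ped$gen[match(kids$sire, ped$id)] == kids$gen - 1L))
  expect_true(all(ped$gen[match(kids$dam, ped$id)] == kids$gen - 1L))
  expect_true(all(ped$sex[match(kids$sire, ped$id)] == "M"))
  expect_true(all(ped$sex[match(kids$dam, ped$id)] == "F"))
  ## phenotypes accumulate from generation 1; base carries none
  expect_true(all(is.na(ped$phen[ped$gen == 0L])))
  expect_true(all(!is.na(ped$phen[ped$gen > 0L])))
  ## exact equal sex ratio in the pre-OCS phases
  for (t in 1:4)
    expect_equal(sum(ped$sex[ped$gen == t] == "M"), 75L)
  ## OCS generations: 15 full-sib families of 10
  for (t in 5:7) {
    fam <- table(paste(kids$sire[kids$gen == t], kids$dam[kids$gen == t]))
    expect_length(fam, 15L)
    expect_true(all(fam == 10L))
  }
  expect_true(all(!is.na(rec$objective[rec$gen %in% 5:7])))
  expect_true(all(is.finite(c(res@dG, res@dFtrue, res@dFped,
                              res@accMale, res@accFemale))))
})

test_that("replicates are bitwise reproducible from the master seed", {
  pools <- reducedPools()
  cfg <- reducedSchemeConfig(truncPredSource = "M", penalty = 5,
                             nGen = 6L, truncGens = 2:3, ocsGens = 4:6,
                             eaBudget = 400L)
  a <- runScheme(pools, cfg, seed = 123L)
  b <- runScheme(pools, cfg, seed = 123L)
  expect_identical(generationRecords(a), generationRecords(b))
  expect_identical(pedigree(a@pop), pedigree(b@pop))
  c <- runScheme(pools, cfg, seed = 124L)
  expect_false(identical(generationRecords(a), generationRecords(c)))
})
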