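test_that("pedigree inbreeding reproduces classical values", {
  ## full sibs mated: offspring F = 0.25; grandparents unrelated
  ped <- data.frame(id = 1:7, sire = c(0, 0, 1, 1, 3, 0, 5),
                    dam = c(0, 0, 2, 2, 4, 0, 6))
  f <- pedigreeInbreeding(ped)
  expect_equal(unname(f[1:2]), c(0, 0))
  expect_equal(unname(f["5"]), 0.25)
  expect_equal(unname(f["7"]), 0)                   # outcross resets F
  expect_error(pedigreeInbreeding(data.frame(id = 1:2, sire = c(2, 0),
                                             dam = c(0, 0))), "sorted")
})

test_that("pedigree inbreeding equals a path-counting oracle", {
  set.seed(33)
  for (rep in 1:5) {
    ped <- data.frame(id = 1:6, sire = 0L, dam = 0L)
    for (i in 7:40) {
      prev <- ped$id
      ped <- rbind(ped, data.frame(id = i, sire = sample(prev, 1),
                                   dam = sample(prev, 1)))
    }
    expect_equal(unname(pedigreeInbreeding(ped)), pathKinshipOracle(ped))
  }
})

test_that("tracer-based inbreeding flags complete autozygosity", {
  pools <- reducedPools()
  set.seed(34)
  pop <- sampleBase(pools, makeTraitModel(pools, "all"), 2L, 2L)
  expect_equal(unname(trueInbreeding(pop)), rep(0, 4))
  pop@I2 <- pop@I1                                  # both genomes one copy
  expect_equal(unname(trueInbreeding(pop)), rep(1, 4))
})

test_that("sire-daughter offspring average the classical F of 0.25", {
  pools <- reducedPools()
  set.seed(35)
  trait <- makeTraitModel(pools, "all")
  pop <- sampleBase(pools, trait, 1L, 1L)
  ## 100 daughters, then 5 offspring from each sire x daughter mating
  pop <- gocsim:::produceOffspring(
    pop, data.frame(sire = rep(1L, 100), dam = rep(2L, 100)),
    trait, 1L, rep("F", 100))
  daughters <- pedigree(pop)$id[pedigree(pop)$gen == 1L]
  pop <- gocsim:::produceOffspring(
    pop, data.frame(sire = 1L, dam = rep(daughters, each = 5)),
    trait, 2L, rep("M", 500))
  ids <- pedigree(pop)$id[pedigree(pop)$gen == 2L]
  famMean <- tapply(trueInbreeding(pop, ids),
                    rep(seq_along(daughters), each = 5), mean)
  se <- sd(famMean) / sqrt(length(famMean))
  expect_lt(abs(mean(famMean) - 0.25), 3 * se + 0.01)
})

test_that("gain and inbreeding rates invert their generating processes", {
  expect_equal(rateOfGain(0.6 * (6:11) + 2, 6:11), 0.6)
  expect_equal(rateOfGain(rep(3, 5)), 0)
  expect_equal(rateOfInbreeding(1 - (1 - 0.01)^(6:11), 6:11), 0.01)
  expect_equal(rateOfInbreeding(rep(0.3, 4)), 0)
  expect_error(rateOfInbreeding(c(0.1, 1, 0.2)), "undefined")
  expect_error(rateOfGain(c(1, 2)), "3 generations")
  ## noisy geometric series recovers the generating rate on average
  set.seed(36)
  est <- replicate(300, {
    f <- 1 - (1 - 0.005)^(6:11) * exp(rnorm(6, 0, 0.002))
    rateOfInbreeding(f, 6:11)
  })
  expect_lt(abs(mean(est) - 0.005), 3 * sd(est) / sqrt(300))
})

test_that("aggregation returns means and standard errors per scenario", {
  reps <- data.frame(scenario = rep(c("Q_M", "M_M"), each = 2),
                     dG = c(0.6, 0.8, 0.4, 0.4))
  agg <- aggregateReplicates(reps)
  qm <- agg[agg$scenario == "Q_M", ]
  expect_equal(qm$dG, 0.7)
  expect_equal(qm$dG_se, 0.1)
  expect_equal(agg[agg$scenario == "M_M", ]$dG_se, 0)
})

test_that("scenario advantages are relative percent differences", {
  tbl <- data.frame(scenario = c("Q_M", "M_M", "A_M"), dG = c(0.6, 0.5, 0.4))
  adv <- scenarioAdvantage(tbl, "Q_M", c("M_M", "A_M"), "dG")
  expect_equal(unname(adv$byAlternative), c(20, 50))
  expect_equal(adv$min, 20)
  expect_equal(adv$max, 50)
  expect_error(scenarioAdvantage(tbl, "Q_A", "M_M", "dG"), "not in table")
})
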