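## small random OCS instance builder
randomOcs <- function(nM = 3L, nF = 4L, nMat = 3L, w = 3) {
  n <- nM + nF
  sex <- rep(c("M", "F"), c(nM, nF))
  W <- matrix(rnorm(n * 10), n)
  G <- tcrossprod(W) / 10 + diag(0.05, n)
  ocsProblem(setNames(rnorm(n), paste0("c", 1:n)), G, sex, w,
             nMatings = nMat, offspringPerMating = 2L)
}

test_that("zero penalty puts all weight on the top candidate per sex", {
  g <- setNames(c(5, 1, 2, 2, 7), c("m1", "m2", "f1", "f2", "f3"))
  prob <- ocsProblem(g, diag(5), rep(c("M", "F"), c(2, 3)), penalty = 0,
                     nMatings = 2L)
  cc <- solveContinuous(prob)
  expect_equal(unname(cc), c(0.5, 0, 0, 0, 0.5))
})

test_that("equal merit with identity G spreads contributions uniformly", {
  n <- 8
  prob <- ocsProblem(setNames(rep(1, n), paste0("x", 1:n)), diag(n),
                     rep(c("M", "F"), each = 4), penalty = 2, nMatings = 3L)
  cc <- solveContinuous(prob)
  expect_equal(unname(cc), rep(0.125, n))
})

test_that("the continuous solver attains the enumerated global optimum", {
  set.seed(22)
  for (rep in 1:12) {
    prob <- randomOcs(w = runif(1, 0.5, 10))
    cc <- solveContinuous(prob)
    expect_equal(sum(cc[prob@sex == "M"]), 0.5, tolerance = 1e-9)
    expect_equal(sum(cc[prob@sex == "F"]), 0.5, tolerance = 1e-9)
    expect_true(all(cc >= -1e-12))
    ora <- bruteContinuousOcs(unname(prob@gebv), prob@G, prob@sex,
                              prob@penalty)
    expect_lt(max(abs(unname(cc) - ora$c)), 1e-6)
  }
})

test_that("evolutionary search equals exhaustive enumeration on tiny instances", {
  set.seed(23)
  for (w in c(0.5, 5, 50)) {                        # gain- to penalty-dominant
    prob <- randomOcs(nM = 3L, nF = 4L, nMat = 3L, w = w)
    sol <- solveInteger(prob, budget = 1200L)
    ora <- solveExhaustive(prob)
    expect_equal(sol@objective, ora@objective, tolerance = 1e-12)
  }
})

test_that("gain-dominant search gives all matings to the best male", {
  ## 2 males (merit 5 and 1), 3 equal dams, identity G, weak penalty
  g <- setNames(c(5, 1, 0, 0, 0), c("m1", "m2", "f1", "f2", "f3"))
  prob <- ocsProblem(g, diag(5) * 0.01, rep(c("M", "F"), c(2, 3)),
                     penalty = 0.1, nMatings = 3L)
  set.seed(24)
  sol <- solveInteger(prob, budget = 600L)
  expect_equal(unname(sol@matings), c(3L, 0L))
  expect_equal(sol@objective, solveExhaustive(prob)@objective)
})

test_that("integer solutions satisfy the contribution identities", {
  set.seed(25)
  prob <- randomOcs(nM = 5L, nF = 8L, nMat = 4L, w = 2)
  sol <- solveInteger(prob, budget = 800L)
  expect_equal(sum(sol@matings), 4L)
  expect_length(unique(sol@dams), 4L)
  cc <- sol@contributions
  expect_equal(sum(cc[prob@sex == "M"]), 0.5)
  expect_equal(sum(cc[prob@sex == "F"]), 0.5)
  expect_equal(unname(cc[names(sol@matings)]), unname(sol@matings) / 8)
  expect_true(all(cc[sol@dams] == 1 / 8))
  ## never below the rounded-continuous or truncation reference plans
  mIdx <- which(prob@sex == "M")
  rp <- gocsim:::roundedPlan(prob, solveContinuous(prob))
  tp <- gocsim:::truncationPlan(prob)
  expect_gte(sol@objective,
             gocsim:::planObjective(prob, rp$m, rp$damIdx, mIdx) - 1e-12)
  expect_gte(sol@objective,
             gocsim:::planObjective(prob, tp$m, tp$damIdx, mIdx) - 1e-12)
})

test_that("stronger penalties realize lower average relationships", {
  set.seed(26)
  n <- 14
  sex <- rep(c("M", "F"), each = 7)
  W <- matrix(rnorm(n * 12), n)
  G <- tcrossprod(W) / 12 + diag(0.05, n)
  g <- rnorm(n)
  cGc <- sapply(c(0.5, 2, 8, 32), function(w) {
    prob <- ocsProblem(setNames(g, paste0("p", 1:n)), G, sex, w,
                       nMatings = 4L)
    set.seed(27)
    cc <- solveInteger(prob, budget = 1200L)@contributions
    as.numeric(cc %*% G %*% cc)
  })
  expect_true(all(diff(cGc) <= 1e-9))
})

test_that("the solver is deterministic given the seed", {
  prob <- { set.seed(28); randomOcs(nM = 4L, nF = 6L, nMat = 3L, w = 2) }
  set.seed(29); a <- solveInteger(prob, budget = 500L)
  set.seed(29); b <- solveInteger(prob, budget = 500L)
  expect_identical(a@matings, b@matings)
  expect_identical(a@dams, b@dams)
  expect_identical(a@objective, b@objective)
})

test_that("mating plans expand counts and use each dam once", {
  sol <- new("ContributionSolution",
             contributions = numeric(0),
             matings = setNames(c(13L, 12L), c("s1", "s2")),
             dams = paste0("d", 1:25), objective = 0, penalty = 1)
  set.seed(30)
  plan <- matingPlan(sol)
  expect_equal(nrow(plan), 25)
  expect_equal(sort(unique(plan$dam)), sort(sol@dams))
  expect_equal(unname(table(plan$sire)[c("s1", "s2")]), c(13L, 12L),
               ignore_attr = TRUE)
  oneSire <- new("ContributionSolution", contributions = numeric(0),
                 matings = setNames(3L, "s9"), dams = paste0("d", 1:3),
                 objective = 0, penalty = 1)
  expect_true(all(matingPlan(oneSire)$sire == "s9"))
})

test_that("penalty calibration converges on a monotone response", {
  ## deterministic synthetic response: dF(w) = 0.03 / (1 + w / 10)
  runFn <- function(w, rep) 0.03 / (1 + w / 10)
  out <- calibrateOmega(runFn, target = 0.01, nReps = 2L, tol = 1e-4,
                        bounds = c(1, 400), maxIter = 20L)
  expect_lt(abs(out$achieved - 0.01), 1e-4)
  expect_lt(abs(out$omega - 20), 1)                 # closed form: w = 20
  ## endpoint hit is returned immediately
  hit <- calibrateOmega(function(w, r) 0.01, 0.01, tol = 1e-3)
  expect_equal(hit$omega, 1)
  ## unreachable targets report the achieved extremes
  expect_error(calibrateOmega(runFn, 0.05, tol = 1e-4, bounds = c(1, 400)),
               "unreachable")
  expect_error(calibrateOmega(runFn, 0.0005, tol = 1e-4, bounds = c(1, 400)),
               "unreachable")
})
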