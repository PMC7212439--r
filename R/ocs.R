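#' @include grm.R
NULL

#' Optimum-contribution selection problem
#'
#' Maximize U(c) = c'ghat - w c'Gc over genetic contributions c, subject to
#' the scheme's mating structure: males contribute c_i = m_i / (2 n_matings)
#' with integer mating counts m_i summing to n_matings, and exactly
#' n_matings dams each contribute 1 / (2 n_matings). Each sex therefore
#' contributes 1/2 in total. The penalty weight `w >= 0` multiplies the
#' average relationship c'Gc of the selected parents (printed penalty
#' values of the form -50, -25, ... correspond to w = 50, 25, ...).
#'
#' @slot gebv named numeric vector of candidate predicted breeding values.
#' @slot G candidate x candidate relationship matrix (same order as gebv).
#' @slot sex character "M"/"F" per candidate.
#' @slot penalty numeric w >= 0.
#' @slot nMatings integer number of matings.
#' @slot offspringPerMating integer offspring per mating.
#' @export
setClass("OcsProblem", representation(
  gebv = "numeric", G = "matrix", sex = "character",
  penalty = "numeric", nMatings = "integer",
  offspringPerMating = "integer"))

setValidity("OcsProblem", function(object) {
  n <- length(object@gebv)
  msg <- character()
  if (!all(dim(object@G) == n))
    msg <- c(msg, "G must be square over the candidates")
  if (length(object@sex) != n || !all(object@sex %in% c("M", "F")))
    msg <- c(msg, "sex must be M/F per candidate")
  if (object@penalty < 0) msg <- c(msg, "penalty weight must be >= 0")
  if (object@nMatings < 1L) msg <- c(msg, "need at least one mating")
  if (sum(object@sex == "M") < 1L)
    msg <- c(msg, "need at least one male candidate")
  if (sum(object@sex == "F") < object@nMatings)
    msg <- c(msg, "need at least nMatings female candidates")
  if (length(msg)) msg else TRUE
})

#' @describeIn OcsProblem-class Constructor.
#' @param gebv,G,sex,penalty,nMatings,offspringPerMating see slots.
#' @export
ocsProblem <- function(gebv, G, sex, penalty, nMatings = 25L,
                       offspringPerMating = 20L) {
  if (is(G, "RelationshipMatrix")) G <- grmValues(G)
  if (is.null(names(gebv))) names(gebv) <- rownames(G)
  new("OcsProblem", gebv = gebv, G = as.matrix(G), sex = as.character(sex),
      penalty = as.numeric(penalty), nMatings = as.integer(nMatings),
      offspringPerMating = as.integer(offspringPerMating))
}

#' Contribution solution
#'
#' @slot contributions named per-candidate contributions (sum 1; 1/2 per
#'   sex).
#' @slot matings named integer mating counts for the males (sum nMatings).
#' @slot dams character ids of the selected dams (length nMatings).
#' @slot objective achieved value of U(c).
#' @slot penalty the penalty weight used.
#' @export
setClass("ContributionSolution", representation(
  contributions = "numeric", matings = "integer", dams = "character",
  objective = "numeric", penalty = "numeric"))

setMethod("show", "ContributionSolution", function(object) {
  cat("ContributionSolution:", sum(object@matings > 0L), "sires,",
      length(object@dams), "dams, objective",
      round(object@objective, 4), "\n")
})

## U(c) for a full-length contribution vector
ocsObjective <- function(prob, cvec) {
  sum(cvec * prob@gebv) - prob@penalty * as.numeric(cvec %*% prob@G %*% cvec)
}

## contribution vector from a mating plan (m over males, dam index set)
planContributions <- function(prob, m, damIdx) {
  cvec <- numeric(length(prob@gebv))
  cvec[prob@sex == "M"] <- m / (2 * prob@nMatings)
  cvec[damIdx] <- 1 / (2 * prob@nMatings)
  names(cvec) <- names(prob@gebv)
  cvec
}

## objective restricted to the plan's support (fast inner loop of the EA)
planObjective <- function(prob, m, damIdx, maleIdx) {
  sup <- c(maleIdx[m > 0L], damIdx)
  cs <- c(m[m > 0L] / (2 * prob@nMatings),
          rep(1 / (2 * prob@nMatings), length(damIdx)))
  sum(cs * prob@gebv[sup]) -
    prob@penalty * as.numeric(cs %*% prob@G[sup, sup, drop = FALSE] %*% cs)
}

#' Continuous relaxation of optimum-contribution selection
#'
#' Maximizes U(c) = c'ghat - w c'Gc subject to the per-sex sum constraints
#' (1/2 each) and c >= 0, by solving the equality-constrained stationarity
#' system on the active set and removing negative candidates until all
#' contributions are non-negative. For w = 0 the objective is linear and
#' the maximum puts all weight of each sex on its highest-gebv candidates.
#'
#' @param prob an [OcsProblem-class].
#' @param ridge ridge added to 2wG if the active-set system is singular.
#' @return named numeric vector of contributions.
#' @export
solveContinuous <- function(prob, ridge = 1e-8) {
  n <- length(prob@gebv)
  sexM <- prob@sex == "M"
  if (prob@penalty == 0) {
    cvec <- numeric(n)
    for (s in c(TRUE, FALSE)) {
      idx <- which(sexM == s)
      top <- idx[prob@gebv[idx] == max(prob@gebv[idx])]
      cvec[top] <- 0.5 / length(top)
    }
    names(cvec) <- names(prob@gebv)
    return(cvec)
  }
  ## primal active-set loop: solve the equality-constrained stationarity
  ## system on the working set; drop the most-negative candidate; re-admit
  ## a zeroed candidate whose reduced gradient is positive (objective can
  ## still increase); stop when primal and dual feasible
  active <- seq_len(n)
  tol <- 1e-10
  for (iter in seq_len(4L * n + 10L)) {
    na <- length(active)
    A <- rbind(as.numeric(sexM[active]), as.numeric(!sexM[active]))
    if (any(rowSums(A) == 0))
      stop("active set lost one sex entirely; penalty structure infeasible")
    Q <- 2 * prob@penalty * prob@G[active, active, drop = FALSE]
    K <- rbind(cbind(Q, t(A)), cbind(A, matrix(0, 2, 2)))
    rhs <- c(prob@gebv[active], 0.5, 0.5)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      warning("singular active-set system; applying ridge")
      Q <- Q + diag(ridge * mean(diag(Q)) + ridge, na)
      K <- rbind(cbind(Q, t(A)), cbind(A, matrix(0, 2, 2)))
      sol <- solve(K, rhs)
    }
    ca <- sol[seq_len(na)]
    if (any(ca < -tol)) {
      active <- active[-which.min(ca)]
      next
    }
    cvec <- numeric(n)
    cvec[active] <- pmax(ca, 0)
    lam <- sol[na + 1:2]                       # male, female multipliers
    out <- setdiff(seq_len(n), active)
    if (length(out)) {
      grad <- prob@gebv - 2 * prob@penalty * as.vector(prob@G %*% cvec)
      eta <- grad[out] - ifelse(sexM[out], lam[1L], lam[2L])
      if (max(eta) > 1e-8) {
        active <- sort(c(active, out[which.max(eta)]))
        next
      }
    }
    names(cvec) <- names(prob@gebv)
    return(cvec)
  }
  stop("active-set loop failed to converge")
}

## round a continuous solution to a feasible integer plan
roundedPlan <- function(prob, cvec) {
  maleIdx <- which(prob@sex == "M")
  femIdx <- which(prob@sex == "F")
  target <- prob@nMatings
  frac <- cvec[maleIdx] * 2 * target
  m <- floor(frac)
  rem <- target - sum(m)
  if (rem > 0L) {
    ord <- order(frac - m, prob@gebv[maleIdx], decreasing = TRUE)
    add <- ord[seq_len(rem)]
    m[add] <- m[add] + 1L
  } else if (rem < 0L) {
    ord <- order(frac - m, -prob@gebv[maleIdx])
    k <- 0L
    while (rem < 0L) {
      k <- k + 1L
      i <- ord[((k - 1L) %% length(ord)) + 1L]
      if (m[i] > 0L) { m[i] <- m[i] - 1L; rem <- rem + 1L }
    }
  }
  damOrd <- femIdx[order(cvec[femIdx], prob@gebv[femIdx],
                         decreasing = TRUE)]
  list(m = as.integer(m), damIdx = sort(damOrd[seq_len(target)]))
}

## truncation-selection comparator plan: top sires by gebv with matings
## split as evenly as possible, top nMatings dams by gebv
truncationPlan <- function(prob, nSires = 10L) {
  maleIdx <- which(prob@sex == "M")
  femIdx <- which(prob@sex == "F")
  nS <- min(length(maleIdx), nSires, prob@nMatings)
  topM <- maleIdx[order(prob@gebv[maleIdx], decreasing = TRUE)][seq_len(nS)]
  m <- integer(length(maleIdx))
  share <- rep(prob@nMatings %/% nS, nS)
  extra <- prob@nMatings %% nS
  if (extra > 0L) share[seq_len(extra)] <- share[seq_len(extra)] + 1L
  m[match(topM, maleIdx)] <- share
  damIdx <- femIdx[order(prob@gebv[femIdx],
                         decreasing = TRUE)][seq_len(prob@nMatings)]
  list(m = m, damIdx = sort(damIdx))
}

#' Integer optimum-contribution selection by evolutionary search
#'
#' Evolutionary algorithm over (integer male mating vector, selected-dam
#' subset): tournament selection, uniform crossover with repair of the
#' mating-count sum, and mutation moving single matings between sires or
#' swapping single dams. The initial population contains the rounded
#' continuous solution and a truncation-selection plan, and elitism is
#' used, so the returned objective is never below either reference.
#' Deterministic given the R random seed.
#'
#' @param prob an [OcsProblem-class].
#' @param budget approximate number of objective evaluations.
#' @param popSize EA population size.
#' @return A [ContributionSolution-class].
#' @export
solveInteger <- function(prob, budget = 2000L, popSize = 24L) {
  maleIdx <- which(prob@sex == "M")
  femIdx <- which(prob@sex == "F")
  nMale <- length(maleIdx)
  nMat <- prob@nMatings
  evalPlan <- function(p) planObjective(prob, p$m, p$damIdx, maleIdx)

  randomPlan <- function() {
    m <- as.integer(tabulate(sample.int(nMale, nMat, replace = TRUE),
                             nbins = nMale))
    list(m = m, damIdx = sort(sample(femIdx, nMat)))
  }
  repairM <- function(m) {
    d <- sum(m) - nMat
    while (d > 0L) { i <- sample(which(m > 0L), 1L); m[i] <- m[i] - 1L; d <- d - 1L }
    while (d < 0L) { i <- sample.int(length(m), 1L); m[i] <- m[i] + 1L; d <- d + 1L }
    m
  }
  mutate <- function(p) {
    if (runif(1) < 0.7 && any(p$m > 0L)) {
      from <- sample(rep(which(p$m > 0L), 2L), 1L)
      to <- sample.int(nMale, 1L)
      p$m[from] <- p$m[from] - 1L
      p$m[to] <- p$m[to] + 1L
    }
    if (runif(1) < 0.7) {
      outPool <- setdiff(femIdx, p$damIdx)
      if (length(outPool)) {
        drop <- sample(rep(p$damIdx, 2L), 1L)
        add <- sample(rep(outPool, 2L), 1L)
        p$damIdx <- sort(c(setdiff(p$damIdx, drop), add))
      }
    }
    p
  }
  crossover <- function(a, b) {
    pick <- runif(nMale) < 0.5
    m <- as.integer(ifelse(pick, a$m, b$m))
    m <- repairM(m)
    pool <- unique(c(a$damIdx, b$damIdx))
    damIdx <- sort(sample(rep(pool, 2L), nMat))
    while (anyDuplicated(damIdx)) {
      dup <- damIdx[duplicated(damIdx)][1L]
      repl <- setdiff(femIdx, damIdx)
      damIdx <- sort(c(damIdx[-match(dup, damIdx)], sample(rep(repl, 2L), 1L)))
    }
    list(m = m, damIdx = damIdx)
  }

  pop <- list(roundedPlan(prob, solveContinuous(prob)),
              truncationPlan(prob))
  while (length(pop) < popSize) pop[[length(pop) + 1L]] <- randomPlan()
  fit <- vapply(pop, evalPlan, numeric(1))
  evals <- length(pop)
  while (evals < budget) {
    newPop <- pop[order(fit, decreasing = TRUE)[1:2]]   # elitism
    newFit <- sort(fit, decreasing = TRUE)[1:2]
    while (length(newPop) < popSize) {
      i <- sample.int(popSize, 2L); a <- pop[[i[which.max(fit[i])]]]
      j <- sample.int(popSize, 2L); b <- pop[[j[which.max(fit[j])]]]
      child <- if (runif(1) < 0.7) crossover(a, b) else a
      child <- mutate(child)
      newPop[[length(newPop) + 1L]] <- child
      newFit <- c(newFit, evalPlan(child))
      evals <- evals + 1L
    }
    pop <- newPop
    fit <- newFit
  }
  best <- pop[[which.max(fit)]]
  cvec <- planContributions(prob, best$m, best$damIdx)
  mat <- best$m
  names(mat) <- names(prob@gebv)[maleIdx]
  new("ContributionSolution",
      contributions = cvec, matings = mat,
      dams = names(prob@gebv)[best$damIdx],
      objective = max(fit), penalty = prob@penalty)
}

#' Exhaustive integer optimum (tiny instances)
#'
#' Enumerates every integer male mating vector and every dam subset;
#' intended as an independent oracle for [solveInteger()] on instances with
#' a handful of candidates.
#'
#' @param prob an [OcsProblem-class].
#' @return A [ContributionSolution-class].
#' @export
solveExhaustive <- function(prob) {
  maleIdx <- which(prob@sex == "M")
  femIdx <- which(prob@sex == "F")
  nMale <- length(maleIdx)
  nMat <- prob@nMatings
  if (choose(nMat + nMale - 1, nMale - 1) * choose(length(femIdx), nMat) > 2e6)
    stop("instance too large to enumerate")
  compositions <- function(total, k) {
    if (k == 1L) return(matrix(total, 1L, 1L))
    out <- NULL
    for (first in 0:total)
      out <- rbind(out, cbind(first, compositions(total - first, k - 1L)))
    out
  }
  ms <- compositions(nMat, nMale)
  damSets <- utils::combn(femIdx, nMat)
  best <- NULL; bestVal <- -Inf
  for (i in seq_len(nrow(ms))) {
    for (j in seq_len(ncol(damSets))) {
      v <- planObjective(prob, as.integer(ms[i, ]), damSets[, j], maleIdx)
      if (v > bestVal) {
        bestVal <- v
        best <- list(m = as.integer(ms[i, ]), damIdx = damSets[, j])
      }
    }
  }
  mat <- best$m
  names(mat) <- names(prob@gebv)[maleIdx]
  new("ContributionSolution",
      contributions = planContributions(prob, best$m, best$damIdx),
      matings = mat, dams = names(prob@gebv)[best$damIdx],
      objective = bestVal, penalty = prob@penalty)
}

#' Random mating plan from a contribution solution
#'
#' Sire slots are expanded by mating counts and matched to the selected
#' dams by a random permutation; each dam is used exactly once.
#'
#' @param solution a [ContributionSolution-class].
#' @return data.frame with columns `mating`, `sire`, `dam`.
#' @export
matingPlan <- function(solution) {
  sires <- rep(names(solution@matings), solution@matings)
  dams <- sample(solution@dams)
  data.frame(mating = seq_along(dams), sire = sires, dam = dams,
             stringsAsFactors = FALSE)
}

#' Calibrate the coancestry penalty to a target rate of true inbreeding
#'
#' Bisection on log(w): realized inbreeding decreases as the penalty
#' weight grows. Each evaluation averages the realized rate of true
#' inbreeding over `nReps` replicate scheme runs.
#'
#' @param runFn function(omega, repIndex) returning one replicate's realized
#'   rate of true inbreeding.
#' @param target target rate of true inbreeding, in (0, 0.05].
#' @param nReps replicates per penalty evaluation.
#' @param tol convergence tolerance on the achieved mean rate.
#' @param bounds initial bracket for w (positive).
#' @param maxIter maximum bisection steps.
#' @return list: `omega`, `achieved`, `se`, `trace` (data.frame of all
#'   evaluations). If the target lies outside the bracket's achievable
#'   range an error reports the achieved extremes.
#' @export
calibrateOmega <- function(runFn, target, nReps = 2L, tol = 0.002,
                           bounds = c(1, 400), maxIter = 8L) {
  stopifnot(target > 0, target <= 0.05, all(bounds > 0))
  evalAt <- function(w) vapply(seq_len(nReps), function(r) runFn(w, r),
                               numeric(1))
  trace <- data.frame(omega = numeric(), dF = numeric(), se = numeric())
  note <- function(w, v) {
    trace[nrow(trace) + 1L, ] <<- c(w, mean(v), sd(v) / sqrt(length(v)))
    mean(v)
  }
  lo <- min(bounds); hi <- max(bounds)
  fLo <- note(lo, evalAt(lo))   # weak penalty: highest inbreeding
  if (abs(fLo - target) <= tol)
    return(list(omega = lo, achieved = fLo,
                se = trace$se[nrow(trace)], trace = trace))
  if (fLo < target)
    stop(sprintf(
      "target %.4g unreachable: weakest penalty %.3g realizes only %.4g",
      target, lo, fLo))
  fHi <- note(hi, evalAt(hi))
  if (abs(fHi - target) <= tol)
    return(list(omega = hi, achieved = fHi,
                se = trace$se[nrow(trace)], trace = trace))
  if (fHi > target)
    stop(sprintf(
      "target %.4g unreachable: strongest penalty %.3g still realizes %.4g",
      target, hi, fHi))
  best <- if (abs(fLo - target) < abs(fHi - target)) c(lo, fLo) else c(hi, fHi)
  for (k in seq_len(maxIter)) {
    mid <- exp((log(lo) + log(hi)) / 2)
    fMid <- note(mid, evalAt(mid))
    if (abs(fMid - target) < abs(best[2] - target)) best <- c(mid, fMid)
    if (abs(fMid - target) <= tol) break
    if (fMid > target) lo <- mid else hi <- mid
  }
  i <- which.min(abs(trace$dF - target))
  list(omega = trace$omega[i], achieved = trace$dF[i], se = trace$se[i],
       trace = trace)
}
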