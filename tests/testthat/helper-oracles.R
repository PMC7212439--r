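## Independent oracles used by the oracle-equivalence tests. These share no
## code with the implementation paths they check.

## dense GLS solution of the G-BLUP model via explicit V inverse
glsOracle <- function(G, recIdx, y, sigmaG2, sigmaE2) {
  V <- sigmaG2 * G[recIdx, recIdx, drop = FALSE] +
    diag(sigmaE2, length(recIdx))
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  list(mu = mu,
       gebv = as.vector(sigmaG2 * G[, recIdx, drop = FALSE] %*%
                          (Vi %*% (y - mu))))
}

## global continuous-OCS optimum by enumerating every zero-set (KKT face)
bruteContinuousOcs <- function(g, G, sex, w, tol = 1e-10) {
  n <- length(g)
  sexM <- sex == "M"
  best <- NULL
  bestVal <- -Inf
  for (mask in 0:(2^n - 1)) {
    zero <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    act <- setdiff(seq_len(n), zero)
    if (!length(act) || !any(sexM[act]) || !any(!sexM[act])) next
    A <- rbind(as.numeric(sexM[act]), as.numeric(!sexM[act]))
    K <- rbind(cbind(2 * w * G[act, act, drop = FALSE], t(A)),
               cbind(A, matrix(0, 2, 2)))
    sol <- tryCatch(solve(K, c(g[act], 0.5, 0.5)), error = function(e) NULL)
    if (is.null(sol)) next
    ca <- sol[seq_along(act)]
    if (any(ca < -tol)) next
    cv <- numeric(n)
    cv[act] <- pmax(ca, 0)
    val <- sum(cv * g) - w * as.numeric(cv %*% G %*% cv)
    if (val > bestVal) { bestVal <- val; best <- cv }
  }
  list(c = best, objective = bestVal)
}

## naive recursive path-counting kinship; F(i) = kinship(sire, dam)
pathKinshipOracle <- function(ped) {
  sire <- setNames(ped$sire, ped$id)
  dam <- setNames(ped$dam, ped$id)
  kin <- function(a, b) {
    if (a == 0 || b == 0) return(0)
    if (a == b) {
      fa <- if (sire[[as.character(a)]] > 0 && dam[[as.character(a)]] > 0)
        kin(sire[[as.character(a)]], dam[[as.character(a)]]) else 0
      return(0.5 * (1 + fa))
    }
    ## recurse on the younger animal (larger id: parents precede offspring)
    if (a < b) { tmp <- a; a <- b; b <- tmp }
    0.5 * (kin(sire[[as.character(a)]], b) + kin(dam[[as.character(a)]], b))
  }
  vapply(ped$id, function(i) {
    s <- sire[[as.character(i)]]; d <- dam[[as.character(i)]]
    if (s == 0 || d == 0) 0 else kin(s, d)
  }, numeric(1))
}

## single-locus Wright-Fisher Monte-Carlo with one-shot mutation from a
## finite pool of monomorphic loci (marginal model of the founder simulator
## under neutrality)
wfOracle <- function(nLoci, mu, twoN, gens) {
  cnt <- integer(nLoci)
  mutated <- logical(nLoci)
  for (t in seq_len(gens)) {
    segr <- which(cnt > 0L & cnt < twoN)
    cnt[segr] <- rbinom(length(segr), twoN, cnt[segr] / twoN)
    fresh <- which(!mutated)
    nm <- min(rbinom(1L, length(fresh) * twoN, mu), length(fresh))
    if (nm > 0) {
      hit <- fresh[sample.int(length(fresh), nm)]
      cnt[hit] <- 1L
      mutated[hit] <- TRUE
    }
  }
  p <- cnt[cnt > 0 & cnt < twoN] / twoN
  list(freq = p, het = mean(2 * p * (1 - p)), nSeg = length(p))
}
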