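#' @include grm.R
NULL

#' G-BLUP fit
#'
#' Solution of the mixed model y = 1 mu + Z g + e with Var(g) = G sigma_g^2
#' and Var(e) = I sigma_e^2, at known variance components. Every animal in
#' the relationship matrix receives a predicted breeding value, whether or
#' not it has a record.
#'
#' @slot muHat GLS estimate of the overall mean.
#' @slot gebv named numeric vector of predicted breeding values in the
#'   animal order of the relationship matrix.
#' @slot sigmaG2,sigmaE2 variance components used.
#' @export
setClass("GblupFit", representation(
  muHat = "numeric", gebv = "numeric",
  sigmaG2 = "numeric", sigmaE2 = "numeric"))

setMethod("show", "GblupFit", function(object) {
  cat("GblupFit:", length(object@gebv), "animals, mu =",
      round(object@muHat, 4), "\n")
})

#' @describeIn GblupFit-class Predicted breeding values (named by animal).
#' @param fit a [GblupFit-class].
#' @export
gebv <- function(fit) fit@gebv

#' Fit G-BLUP with known variance components
#'
#' Solves in the observed-data form: with records y on animals r,
#' V = sigma_g^2 G[r,r] + sigma_e^2 I, mu-hat the GLS mean, and
#' g-hat = sigma_g^2 G[, r] V^-1 (y - 1 mu-hat). This tolerates singular G
#' (e.g. a QTL-based G of low rank), since V is always positive definite
#' for sigma_e^2 > 0.
#'
#' @param records data.frame with columns `animal` (id matching the
#'   relationship matrix) and `y` (phenotype).
#' @param g a [RelationshipMatrix-class] containing every recorded animal.
#' @param sigmaG2,sigmaE2 additive and residual variances (defaults 1, 4).
#' @return A [GblupFit-class].
#' @export
fitGblup <- function(records, g, sigmaG2 = 1, sigmaE2 = 4) {
  if (nrow(records) == 0L) stop("no phenotype records")
  if (any(!is.finite(records$y))) stop("non-finite phenotypes")
  if (sigmaG2 < 0 || sigmaE2 <= 0)
    stop("need sigmaG2 >= 0 and sigmaE2 > 0")
  r <- match(as.character(records$animal), g@animalIds)
  if (anyNA(r)) stop("recorded animal missing from the relationship matrix")
  y <- records$y
  n <- length(y)
  V <- sigmaG2 * g@values[r, r, drop = FALSE] + diag(sigmaE2, n)
  cV <- chol(V)
  solveV <- function(b) backsolve(cV, forwardsolve(t(cV), b))
  Vi1 <- solveV(rep(1, n))
  mu <- sum(Vi1 * y) / sum(Vi1)
  w <- solveV(y - mu)
  ghat <- as.vector(sigmaG2 * g@values[, r, drop = FALSE] %*% w)
  names(ghat) <- g@animalIds
  new("GblupFit", muHat = mu, gebv = ghat,
      sigmaG2 = sigmaG2, sigmaE2 = sigmaE2)
}

#' Accuracy of predicted breeding values
#'
#' Pearson correlation between predictions and true breeding values over a
#' group of animals.
#'
#' @param fit a [GblupFit-class] (or a named numeric vector of
#'   predictions).
#' @param tbv named numeric vector of true breeding values.
#' @param group animal ids to evaluate over (default: all names of `tbv`).
#' @return correlation, or NA with a warning if the predictions have zero
#'   variance in the group.
#' @export
accuracy <- function(fit, tbv, group = names(tbv)) {
  pred <- if (is(fit, "GblupFit")) fit@gebv else fit
  group <- as.character(group)
  if (!length(group)) stop("empty group")
  p <- pred[group]
  t <- tbv[group]
  if (anyNA(p) || anyNA(t)) stop("group members missing predictions or TBV")
  if (sd(t) == 0) stop("zero TBV variance in group")
  if (sd(p) == 0) {
    warning("zero variance of predictions in group; accuracy undefined")
    return(NA_real_)
  }
  cor(p, t)
}
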