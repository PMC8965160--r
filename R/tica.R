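## featurize_cluster module, part 1: time-lagged independent component
## analysis (TICA).

## Extract the raw matrix from a FeatureTrajectory or pass a matrix through.
asTrajMatrix <- function(tr) {
  if (is(tr, "FeatureTrajectory")) tr@X else as.matrix(tr)
}

#' Fit a TICA model
#'
#' Solves the generalized eigenproblem of the symmetrized time-lagged
#' covariance against the instantaneous covariance after mean removal. Both
#' covariances average over the time-shifted frame pairs of every trajectory;
#' the lagged covariance is symmetrized (average with its transpose) so the
#' spectrum is real on finite data, and the instantaneous covariance receives
#' a ridge of `1e-8 * trace/F` on its diagonal so constant or collinear
#' features are regularized out rather than producing NaNs (a warning is
#' emitted when near-singular directions are detected). Components are
#' orthonormal under the instantaneous covariance. The number of retained
#' components is the smallest k whose cumulative squared eigenvalues reach
#' `varianceFraction` of the total kinetic variance (sum of all squared
#' eigenvalues).
#'
#' @param trajs list of [FeatureTrajectory-class] (or plain matrices).
#' @param lag lag in frames (>= 1, shorter than every trajectory).
#' @param varianceFraction kinetic variance fraction to retain, in (0, 1].
#' @return a [TicaModel-class].
#' @export
fitTica <- function(trajs, lag, varianceFraction = 0.95) {
  if (!is.list(trajs)) trajs <- list(trajs)
  Xs <- lapply(trajs, asTrajMatrix)
  lag <- as.integer(lag)
  Fdim <- ncol(Xs[[1]])
  if (Fdim < 2) stop("TICA needs at least 2 features")
  if (lag < 1) stop("lag must be >= 1")
  if (any(vapply(Xs, nrow, 1L) <= lag))
    stop("lag must be shorter than every trajectory")

  ## pooled mean over all frames
  ntot <- sum(vapply(Xs, nrow, 1L))
  mu <- Reduce(`+`, lapply(Xs, colSums)) / ntot

  C0 <- matrix(0, Fdim, Fdim)
  Ct <- matrix(0, Fdim, Fdim)
  npairs <- 0
  for (X in Xs) {
    Xc <- sweep(X, 2, mu)
    n <- nrow(Xc)
    A <- Xc[1:(n - lag), , drop = FALSE]
    B <- Xc[(1 + lag):n, , drop = FALSE]
    C0 <- C0 + (crossprod(A) + crossprod(B)) / 2
    Ct <- Ct + (crossprod(A, B) + crossprod(B, A)) / 2
    npairs <- npairs + (n - lag)
  }
  C0 <- C0 / npairs
  Ct <- Ct / npairs

  dvar <- diag(C0)
  if (any(dvar < 1e-12 * max(mean(dvar), .Machine$double.eps)))
    warning("near-singular instantaneous covariance; applying diagonal regularization")
  eps <- 1e-8 * sum(diag(C0)) / Fdim
  C0 <- C0 + diag(eps, Fdim)

  W <- symInvSqrt(C0)
  M <- W %*% Ct %*% W
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  lambda <- e$values[ord]
  lambda <- pmin(pmax(lambda, -1), 1)   # clamp numerical overshoot
  U <- W %*% e$vectors[, ord, drop = FALSE]   # orthonormal under C0

  kinetic <- lambda^2
  total <- sum(kinetic)
  frac <- if (total > 0) cumsum(kinetic) / total else rep(1, Fdim)
  k <- which(frac >= varianceFraction - 1e-12)[1]
  if (is.na(k)) k <- Fdim

  comp <- U[, seq_len(k), drop = FALSE]
  rownames(comp) <- colnames(Xs[[1]])
  new("TicaModel", lag = lag, mean = mu, eigenvalues = lambda,
      components = comp, kineticVarianceFraction = frac[k],
      requestedFraction = varianceFraction)
}

#' Project trajectories onto TICA components
#'
#' @param model a [TicaModel-class].
#' @param trajs list of [FeatureTrajectory-class] (or matrices) with the same
#'   features the model was fitted on.
#' @return list of [FeatureTrajectory-class] in tic coordinates (features
#'   named "tic1", "tic2", ...); plain matrices in, plain matrices out.
#' @export
ticaTransform <- function(model, trajs) {
  single <- !is.list(trajs)
  if (single) trajs <- list(trajs)
  out <- lapply(trajs, function(tr) {
    X <- asTrajMatrix(tr)
    Y <- sweep(X, 2, model@mean) %*% model@components
    colnames(Y) <- paste0("tic", seq_len(ncol(Y)))
    if (is(tr, "FeatureTrajectory")) {
      new("FeatureTrajectory", trajectoryId = tr@trajectoryId,
          frameDt = tr@frameDt, X = Y, featureNames = colnames(Y),
          hiddenStates = tr@hiddenStates)
    } else Y
  })
  if (single) out[[1]] else out
}
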