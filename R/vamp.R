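## featurize_cluster module, part 3: VAMP2 scoring of discretizations.

## Collect (s_t, s_{t+lag}) pairs from integer assignment sequences.
lagPairs <- function(dtrajs, lag) {
  pairs <- lapply(dtrajs, function(s) {
    n <- length(s)
    if (n <= lag) return(NULL)
    cbind(s[1:(n - lag)], s[(1 + lag):n])
  })
  do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
}

## Half-weighted propagator K = C00^{-1/2} C0t Ctt^{-1/2} for indicator
## (one-hot) state features, restricted to `states`. With one-hot features the
## covariances are diagonal marginal counts and the pair-count matrix.
halfWeightedPropagator <- function(pairs, states) {
  idx <- match(pairs, states)
  dim(idx) <- dim(pairs)
  keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  idx <- idx[keep, , drop = FALSE]
  K <- length(states)
  C <- matrix(tabulate(idx[, 1] + (idx[, 2] - 1L) * K, K * K), K, K)
  r <- rowSums(C); c <- colSums(C)
  C / sqrt(outer(pmax(r, 1e-300), pmax(c, 1e-300)))
}

#' VAMP2 score of a discretization
#'
#' Estimates the half-weighted propagator of the discrete jump process at the
#' given lag (one-hot state features, empirical weights) and returns the sum
#' of its top `nProcesses` squared singular values -- the kinetic variance
#' captured by the discretization. The stationary process contributes 1, so
#' the score lies in \[1, nProcesses\]. If the discrete count graph is
#' disconnected the score is computed on the largest strongly connected set,
#' with a warning.
#'
#' @param disc a [Discretization-class], or a list of integer assignment
#'   sequences.
#' @param lag lag in frames.
#' @param nProcesses number of singular values summed (<= number of states).
#' @return the VAMP2 score (>= 1 up to sampling noise).
#' @export
vamp2Score <- function(disc, lag, nProcesses = 10L) {
  dtrajs <- if (is(disc, "Discretization")) disc@assignments else disc
  pairs <- lagPairs(dtrajs, lag)
  if (is.null(pairs)) stop("no trajectory longer than the lag")
  K <- max(pairs)
  C <- matrix(tabulate(pairs[, 1] + (pairs[, 2] - 1L) * K, K * K), K, K)
  scc <- largestSCC(C)
  present <- sort(unique(as.vector(pairs)))
  if (length(scc) < length(present))
    warning("disconnected discretization; restricting to largest connected set (",
            length(scc), " of ", length(present), " states)")
  Khat <- halfWeightedPropagator(pairs, scc)
  sv <- svd(Khat, nu = 0, nv = 0)$d
  sum(head(sv, min(nProcesses, length(sv)))^2)
}

#' Cross-validated VAMP2 score
#'
#' Splits trajectories into folds, estimates the top singular functions of
#' the half-weighted propagator on the training fold, and scores them on the
#' held-out fold; the mean over folds estimates out-of-sample kinetic
#' variance and guards hyperparameter selection (cluster count, tic variance)
#' against overfitting.
#'
#' @param disc a [Discretization-class] or list of assignment sequences (>= 2
#'   trajectories).
#' @param lag lag in frames.
#' @param nProcesses number of singular functions scored.
#' @param nFolds folds over trajectories.
#' @param seed integer seed for the fold split.
#' @return mean held-out VAMP2 score.
#' @export
vamp2ScoreCV <- function(disc, lag, nProcesses = 10L, nFolds = 2L, seed = 1L) {
  dtrajs <- if (is(disc, "Discretization")) disc@assignments else disc
  if (length(dtrajs) < nFolds) stop("need at least as many trajectories as folds")
  folds <- withSeed(deriveSeed(seed, 3L),
                    sample(rep_len(seq_len(nFolds), length(dtrajs))))
  scores <- vapply(seq_len(nFolds), function(f) {
    train <- lagPairs(dtrajs[folds != f], lag)
    test <- lagPairs(dtrajs[folds == f], lag)
    if (is.null(train) || is.null(test)) return(NA_real_)
    Ctr <- {
      K <- max(train)
      matrix(tabulate(train[, 1] + (train[, 2] - 1L) * K, K * K), K, K)
    }
    states <- largestSCC(Ctr)
    n <- min(nProcesses, length(states))
    Ktr <- halfWeightedPropagator(train, states)
    sv <- svd(Ktr, nu = n, nv = n)
    ## singular functions in state space (whitened by training marginals)
    idx <- match(train, states); dim(idx) <- dim(train)
    keep <- !is.na(idx[, 1]) & !is.na(idx[, 2]); idx <- idx[keep, , drop = FALSE]
    r <- tabulate(idx[, 1], length(states)); cc <- tabulate(idx[, 2], length(states))
    L <- sv$u / sqrt(pmax(r, 1))
    R <- sv$v / sqrt(pmax(cc, 1))
    ## test covariances of those functions
    ti <- match(test, states); dim(ti) <- dim(test)
    keep <- !is.na(ti[, 1]) & !is.na(ti[, 2]); ti <- ti[keep, , drop = FALSE]
    if (!nrow(ti)) return(NA_real_)
    Kt <- length(states)
    Cte <- matrix(tabulate(ti[, 1] + (ti[, 2] - 1L) * Kt, Kt * Kt), Kt, Kt) / nrow(ti)
    r2 <- rowSums(Cte); c2 <- colSums(Cte)
    C00 <- t(L) %*% (L * r2)
    Ctt <- t(R) %*% (R * c2)
    C0t <- t(L) %*% Cte %*% R
    ## ridge against singular-function directions unsupported in the test
    ## fold; singular values are clipped at their theoretical bound of 1
    eps <- 1e-4
    C00 <- C00 + diag(eps * mean(diag(C00)), n)
    Ctt <- Ctt + diag(eps * mean(diag(Ctt)), n)
    M <- symInvSqrt(C00) %*% C0t %*% symInvSqrt(Ctt)
    sum(pmin(head(svd(M, nu = 0, nv = 0)$d, n), 1)^2)
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}
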