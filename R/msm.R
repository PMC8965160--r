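## msm_core module: transition counting, MSM estimation, implied timescales,
## state free energies, weighted landscapes, conditional probabilities.

#' Count state-to-state transitions
#'
#' Counts observed (state at t, state at t + lag) pairs in every trajectory;
#' trajectories are never concatenated across boundaries. `"sliding"` counts
#' all t, `"strided"` only t = 0, lag, 2 lag, ...
#'
#' @param dtrajs list of integer state sequences (1-based), or a
#'   [Discretization-class].
#' @param lag lag in frames (>= 1).
#' @param mode "sliding" (default) or "strided".
#' @param nStates matrix dimension; defaults to the largest observed state.
#' @return a [CountMatrix-class].
#' @export
countTransitions <- function(dtrajs, lag, mode = c("sliding", "strided"),
                             nStates = NULL) {
  mode <- match.arg(mode)
  if (is(dtrajs, "Discretization")) dtrajs <- dtrajs@assignments
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lag <- as.integer(lag)
  if (lag < 1) stop("lag must be >= 1")
  if (all(lengths(dtrajs) <= lag))
    stop("no trajectory longer than the lag (", lag, ")")
  K <- if (is.null(nStates)) max(unlist(dtrajs, use.names = FALSE)) else as.integer(nStates)
  C <- matrix(0, K, K)
  for (s in dtrajs) {
    n <- length(s)
    if (n <= lag) next
    t0 <- if (mode == "sliding") 1:(n - lag) else seq.int(1L, n - lag, by = lag)
    i <- s[t0]; j <- s[t0 + lag]
    C <- C + matrix(tabulate(i + (j - 1L) * K, K * K), K, K)
  }
  new("CountMatrix", counts = C, lag = lag, countingMode = mode)
}

#' Estimate a Markov state model
#'
#' Restricts the count matrix to the largest strongly connected component of
#' its count graph (the active set), row-normalizes the counts to the
#' transition matrix T_ij = C_ij / sum_j C_ij, and computes the stationary
#' distribution as the leading left eigenvector normalized to sum 1. The
#' estimator is the plain (non-reversible) maximum-likelihood row
#' normalization; `reversible = TRUE` symmetrizes the counts
#' (C + t(C)) / 2 before normalization, which enforces detailed balance.
#'
#' @param C a [CountMatrix-class] (or plain count matrix, counted at `lag`).
#' @param frameDt nanoseconds per frame.
#' @param lag lag in frames, required when `C` is a plain matrix.
#' @param reversible enforce detailed balance by count symmetrization.
#' @return a [MarkovStateModel-class].
#' @export
estimateMSM <- function(C, frameDt = 1.0, lag = NULL, reversible = FALSE) {
  if (!is(C, "CountMatrix")) {
    if (is.null(lag)) stop("lag required when C is a plain matrix")
    C <- new("CountMatrix", counts = as.matrix(C), lag = as.integer(lag),
             countingMode = "sliding")
  }
  Cm <- C@counts
  active <- largestSCC(Cm)
  if (!length(active)) stop("empty active set")
  Ca <- Cm[active, active, drop = FALSE]
  if (isTRUE(reversible)) Ca <- (Ca + t(Ca)) / 2
  rs <- rowSums(Ca)
  stopifnot(all(rs > 0))   # impossible after SCC restriction
  T <- Ca / rs
  ## exact row-stochasticity to machine precision
  T <- T / rowSums(T)
  pi <- statDist(T)
  new("MarkovStateModel", T = T, pi = pi, activeSet = as.integer(active),
      lag = C@lag, frameDt = frameDt, countMatrix = C)
}

#' Implied timescales from a transition matrix
#'
#' Computes t_i = -tau / ln(lambda_i) for the eigenvalues of T below 1, with
#' tau = lag * frameDt. Non-positive or complex eigenvalues are reported as
#' NA (the associated processes have no real relaxation time); eigenvalues
#' at or above 1 beyond the stationary one are reported as +Inf.
#'
#' @param T row-stochastic matrix.
#' @param lag lag in frames.
#' @param frameDt nanoseconds per frame.
#' @param nTimescales number of process timescales returned.
#' @return numeric vector of timescales in ns, slowest first.
#' @export
timescalesFromTransitionMatrix <- function(T, lag, frameDt = 1.0,
                                           nTimescales = nrow(T) - 1L) {
  ev <- eigen(T, only.values = TRUE)$values
  ev <- ev[order(-Mod(ev))]
  ev <- ev[-1]                       # drop the stationary eigenvalue
  n <- min(nTimescales, length(ev))
  tau <- lag * frameDt
  vapply(seq_len(n), function(i) {
    l <- ev[i]
    if (abs(Im(l)) > 1e-10) return(NA_real_)
    l <- Re(l)
    if (l <= 0) return(NA_real_)
    if (l >= 1 - 1e-14) return(Inf)
    -tau / log(l)
  }, numeric(1))
}

#' Implied timescales across lags
#'
#' Estimates an MSM at every lag and reports the relaxation timescales
#' t = -tau / ln(lambda). Lag selection looks for logarithmic convergence of
#' these curves: once timescales stop changing with the lag, the model is
#' Markovian at that lag.
#'
#' @param dtrajs list of integer state sequences or a [Discretization-class].
#' @param lags integer vector of lags in frames.
#' @param nTimescales processes per lag.
#' @param frameDt nanoseconds per frame.
#' @param mode counting mode passed to [countTransitions()].
#' @return data.frame with columns lag, process, timescaleNs.
#' @export
impliedTimescales <- function(dtrajs, lags, nTimescales = 5L, frameDt = 1.0,
                              mode = "sliding") {
  rows <- lapply(lags, function(lg) {
    msm <- estimateMSM(countTransitions(dtrajs, lg, mode), frameDt)
    ts <- timescalesFromTransitionMatrix(msm@T, lg, frameDt,
                                         min(nTimescales, nrow(msm@T) - 1L))
    if (!length(ts)) return(NULL)
    data.frame(lag = lg, process = seq_along(ts) + 1L, timescaleNs = ts)
  })
  do.call(rbind, rows)
}

#' State free energies from populations
#'
#' G_i = -k_B T ln(pi_i) with k_B = 0.0019872 kcal/mol/K, shifted so the
#' lowest populated state sits at 0. Zero-population states are NA (masked),
#' not -Inf.
#'
#' @param pi stationary probabilities.
#' @param temperature Kelvin (default 300).
#' @return per-state free energies in kcal/mol.
#' @export
freeEnergyOfStates <- function(pi, temperature = 300) {
  stopifnot(temperature > 0)
  G <- ifelse(pi > 0, -.kB * temperature * log(pi), NA_real_)
  G - min(G, na.rm = TRUE)
}

## Per-frame MSM weights: w = pi[state] / (frames observed in that state);
## frames assigned to states outside the active set get zero weight. Returns
## a list of per-trajectory weight vectors summing to 1 overall.
frameWeights <- function(msm, disc, trajs = NULL) {
  dtrajs <- if (is(disc, "Discretization")) disc@assignments else disc
  K <- nrow(msm@countMatrix@counts)
  toActive <- rep(NA_integer_, K)
  toActive[msm@activeSet] <- seq_along(msm@activeSet)
  counts <- tabulate(unlist(lapply(dtrajs, function(s) toActive[s]), use.names = FALSE),
                     length(msm@activeSet))
  lapply(dtrajs, function(s) {
    a <- toActive[s]
    w <- ifelse(is.na(a) | counts[ifelse(is.na(a), 1L, a)] == 0, 0,
                msm@pi[ifelse(is.na(a), 1L, a)] / counts[ifelse(is.na(a), 1L, a)])
    w
  })
}

## Pull a named observable column from each trajectory.
observableColumn <- function(trajs, name) {
  lapply(trajs, function(tr) {
    X <- asTrajMatrix(tr)
    nm <- if (is(tr, "FeatureTrajectory")) tr@featureNames else colnames(X)
    j <- match(name, nm)
    if (is.na(j)) stop("observable '", name, "' not found in trajectory features")
    X[, j]
  })
}

#' MSM-weighted free-energy landscape
#'
#' Weights every frame by the equilibrium probability of its state divided by
#' the number of frames observed in that state (so each state's population is
#' spread over its frames), histograms the weights over one or two
#' observables, and converts to free energy
#' G_bin = -k_B T ln(w_bin / max w_bin). Empty bins are masked. This removes
#' the sampling bias of adaptive restarting from the landscape.
#'
#' @param msm a [MarkovStateModel-class].
#' @param disc the [Discretization-class] aligned with `trajs`.
#' @param trajs list of [FeatureTrajectory-class].
#' @param obsX,obsY observable feature names (`obsY = NULL` for a 1-D
#'   profile).
#' @param bins bin count (scalar or length 2).
#' @param temperature Kelvin.
#' @return a [FreeEnergySurface-class].
#' @export
weightedLandscape <- function(msm, disc, trajs, obsX, obsY = NULL,
                              bins = 50L, temperature = 300) {
  w <- unlist(frameWeights(msm, disc), use.names = FALSE)
  x <- unlist(observableColumn(trajs, obsX), use.names = FALSE)
  stopifnot(length(x) == length(w))
  bins <- rep_len(as.integer(bins), 2L)
  rngPad <- function(v) {
    r <- range(v); if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    r + c(0, 1e-9 * max(1, abs(r[2])))
  }
  rx <- rngPad(x)
  xEdges <- seq(rx[1], rx[2], length.out = bins[1] + 1L)
  bx <- pmin(pmax(findInterval(x, xEdges, rightmost.closed = TRUE), 1L), bins[1])
  if (is.null(obsY)) {
    wbin <- vapply(seq_len(bins[1]), function(b) sum(w[bx == b]), numeric(1))
    mask <- wbin <= 0
    G <- ifelse(mask, NA_real_, -.kB * temperature * log(wbin / max(wbin)))
    return(new("FreeEnergySurface", xEdges = xEdges, yEdges = numeric(0),
               G = G, mask = mask, temperature = temperature))
  }
  y <- unlist(observableColumn(trajs, obsY), use.names = FALSE)
  ry <- rngPad(y)
  yEdges <- seq(ry[1], ry[2], length.out = bins[2] + 1L)
  by <- pmin(pmax(findInterval(y, yEdges, rightmost.closed = TRUE), 1L), bins[2])
  flat <- bx + (by - 1L) * bins[1]
  wbin <- vapply(seq_len(bins[1] * bins[2]), function(b) 0, numeric(1))
  agg <- tapply(w, flat, sum)
  wbin[as.integer(names(agg))] <- agg
  Wm <- matrix(wbin, bins[1], bins[2])
  mask <- Wm <= 0
  G <- ifelse(mask, NA_real_, -.kB * temperature * log(Wm / max(Wm)))
  new("FreeEnergySurface", xEdges = xEdges, yEdges = yEdges,
      G = G, mask = mask, temperature = temperature)
}

#' Free-energy gap between the minima of a 1-D profile
#'
#' Splits a 1-D [FreeEnergySurface-class] at `at` (observable units) and
#' returns G(min right) - G(min left): the free-energy difference between the
#' two basins.
#'
#' @param surface a 1-D [FreeEnergySurface-class].
#' @param at split point.
#' @return gap in kcal/mol.
#' @export
basinGap <- function(surface, at = 0) {
  stopifnot(length(surface@yEdges) == 0)
  mid <- (surface@xEdges[-1] + surface@xEdges[-length(surface@xEdges)]) / 2
  G <- surface@G
  min(G[mid >= at], na.rm = TRUE) - min(G[mid < at], na.rm = TRUE)
}

#' MSM-weighted conditional probability
#'
#' P(outcome | condition) = W(condition and outcome) / W(condition), where W
#' sums the MSM frame weights (see [weightedLandscape()]). Predicates are
#' functions of a trajectory's feature matrix returning one logical per
#' frame.
#'
#' @param msm a [MarkovStateModel-class].
#' @param disc the aligned [Discretization-class].
#' @param trajs list of [FeatureTrajectory-class].
#' @param condition,outcome frame predicates: `function(X)` -> logical
#'   vector, with `X` the frames x features matrix (named columns).
#' @return probability in \[0, 1\].
#' @export
conditionalProbability <- function(msm, disc, trajs, condition, outcome) {
  w <- frameWeights(msm, disc)
  num <- 0; den <- 0
  for (i in seq_along(trajs)) {
    X <- asTrajMatrix(trajs[[i]])
    colnames(X) <- if (is(trajs[[i]], "FeatureTrajectory"))
      trajs[[i]]@featureNames else colnames(X)
    cnd <- as.logical(condition(X))
    out <- as.logical(outcome(X))
    den <- den + sum(w[[i]][cnd])
    num <- num + sum(w[[i]][cnd & out])
  }
  if (den <= 0) stop("condition has zero MSM weight")
  num / den
}

#' Map clusters to hidden states by majority vote
#'
#' For synthetic data with known hidden state paths: each cluster is mapped
#' to the hidden state contributing most of its frames. Used in recovery
#' studies to coarse-grain a discretization back onto the generating chain.
#'
#' @param disc a [Discretization-class].
#' @param trajs the generating [FeatureTrajectory-class] list (with hidden
#'   states).
#' @return integer vector: cluster index -> hidden state.
#' @export
majorityVoteMap <- function(disc, trajs) {
  cl <- unlist(disc@assignments, use.names = FALSE)
  hid <- unlist(lapply(trajs, function(tr) tr@hiddenStates), use.names = FALSE)
  stopifnot(length(cl) == length(hid))
  vapply(seq_len(disc@K), function(k) {
    h <- hid[cl == k]
    if (!length(h)) return(NA_integer_)
    tab <- tabulate(h)
    which.max(tab)
  }, integer(1))
}

#' Coarse-grain assignment sequences through a cluster map
#'
#' @param disc a [Discretization-class].
#' @param map integer vector from [majorityVoteMap()].
#' @return list of relabelled integer sequences.
#' @export
coarseGrainAssignments <- function(disc, map) {
  lapply(disc@assignments, function(s) map[s])
}
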