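## kinetics module: macrostate definition, transition-path-theory
## committor/flux/MFPT, and kinetic Monte Carlo on the MSM.

#' Define a macrostate from a region of state space
#'
#' Among active-set states whose cluster centers satisfy the region
#' predicate, selects the `nTop` states with the highest raw frame count
#' (ties broken by lower state index). If fewer than `nTop` states qualify,
#' all of them are taken with a warning. This mirrors the practice of
#' defining a macrostate as the few most-populated model states inside a
#' region of interest on a landscape.
#'
#' @param msm a [MarkovStateModel-class].
#' @param disc the [Discretization-class] the MSM was counted on.
#' @param region predicate `function(center)` -> logical, evaluated on each
#'   active state's cluster center (named by discretization dimensions).
#' @param nTop number of states to keep (default 5).
#' @param name macrostate label.
#' @return a [MacrostateSet-class] holding positions within the active set.
#' @export
defineMacrostate <- function(msm, disc, region, nTop = 5L, name = "macrostate") {
  counts <- tabulate(unlist(disc@assignments, use.names = FALSE),
                     nrow(msm@countMatrix@counts))
  centers <- disc@centers[msm@activeSet, , drop = FALSE]
  sel <- which(vapply(seq_len(nrow(centers)),
                      function(i) isTRUE(region(centers[i, ])), logical(1)))
  if (!length(sel)) stop("region selects no active state")
  rawCounts <- counts[msm@activeSet[sel]]
  ord <- sel[order(-rawCounts, sel)]
  if (length(ord) < nTop)
    warning("region holds only ", length(ord), " states (requested ", nTop, ")")
  states <- sort(head(ord, nTop))
  new("MacrostateSet", name = name, states = as.integer(states),
      definition = sprintf("top %d of %d qualifying states by raw count",
                           length(states), length(sel)))
}

#' Simple macrostate from explicit states
#'
#' @param states positions within the MSM active set.
#' @param name label.
#' @return a [MacrostateSet-class].
#' @export
macrostate <- function(states, name = "macrostate") {
  stopifnot(length(states) >= 1)
  new("MacrostateSet", name = name, states = as.integer(sort(unique(states))),
      definition = "explicit state list")
}

.asStates <- function(x) if (is(x, "MacrostateSet")) x@states else as.integer(x)

#' Forward committor
#'
#' Probability q+_i that a trajectory in state i reaches the sink macrostate
#' before the source macrostate: q+ = 0 on the source, 1 on the sink, and on
#' interior states it solves the linear system q_i = sum_j T_ij q_j.
#'
#' @param T row-stochastic transition matrix.
#' @param source,sink disjoint, non-empty state index sets.
#' @return committor vector over all states.
#' @export
committor <- function(T, source, sink) {
  A <- .asStates(source); B <- .asStates(sink)
  n <- nrow(T)
  if (!length(A) || !length(B)) stop("source and sink must be non-empty")
  if (length(intersect(A, B))) stop("source and sink must be disjoint")
  interior <- setdiff(seq_len(n), c(A, B))
  q <- numeric(n)
  q[B] <- 1
  if (length(interior)) {
    ## states that cannot reach the sink make the system singular; name them
    g <- igraph::graph_from_adjacency_matrix((T > 0) * 1, mode = "directed")
    d <- igraph::distances(g, v = interior, to = B, mode = "out")
    unreachable <- interior[apply(d, 1, function(r) all(!is.finite(r)))]
    if (length(unreachable))
      stop("sink unreachable from state(s): ", paste(unreachable, collapse = ", "))
    M <- diag(length(interior)) - T[interior, interior, drop = FALSE]
    b <- rowSums(T[interior, B, drop = FALSE])
    q[interior] <- solve(M, b)
  }
  pmin(pmax(q, 0), 1)
}

#' Backward committor
#'
#' Probability that the process, viewed backward in time, reaches the source
#' before the sink: computed as the forward committor of the time-reversed
#' chain T~_ij = pi_j T_ji / pi_i with the roles of source and sink swapped.
#'
#' @param T row-stochastic matrix; @param pi its stationary distribution.
#' @param source,sink state index sets.
#' @return backward committor vector (1 on source, 0 on sink).
#' @export
backwardCommittor <- function(T, pi, source, sink) {
  Trev <- t(T * pi) / pi
  committor(Trev, source = .asStates(sink), sink = .asStates(source))
}

#' Reactive flux between two macrostates
#'
#' F_AB = sum over i in A, j not in A of pi_i T_ij q+_j: the net probability
#' current of reactive source-to-sink transitions per lag step.
#'
#' @param msm a [MarkovStateModel-class].
#' @param source,sink macrostates (sets of active-set positions).
#' @return non-negative flux per lag step.
#' @export
reactiveFlux <- function(msm, source, sink) {
  A <- .asStates(source); B <- .asStates(sink)
  q <- committor(msm@T, A, B)
  notA <- setdiff(seq_len(nrow(msm@T)), A)
  sum(outer(msm@pi[A], rep(1, length(notA))) *
        msm@T[A, notA, drop = FALSE] *
        outer(rep(1, length(A)), q[notA]))
}

#' Mean first-passage time between macrostates
#'
#' MFPT = tau * pi_A / F_AB with pi_A the stationary probability of the
#' source macrostate and tau the MSM lag. Reported in frames and
#' nanoseconds. Note that other transition-path-theory conventions normalize
#' the rate by sum_i pi_i q-_i instead of pi_A; the two agree when the
#' source and sink partition the state space (in particular for two-state
#' systems) and whenever intermediate states carry little population.
#'
#' @param msm a [MarkovStateModel-class].
#' @param source,sink macrostates.
#' @return list with `frames`, `ns`, `flux`, `piA`.
#' @export
mfpt <- function(msm, source, sink) {
  A <- .asStates(source)
  Fab <- reactiveFlux(msm, source, sink)
  if (Fab <= 0) stop("zero reactive flux; sink unreachable from source")
  piA <- sum(msm@pi[A])
  frames <- msm@lag * piA / Fab
  list(frames = frames, ns = frames * msm@frameDt, flux = Fab, piA = piA)
}

#' Full transition-path-theory analysis
#'
#' @param msm a [MarkovStateModel-class].
#' @param source,sink [MacrostateSet-class]s (or state index vectors).
#' @return a [TPTResult-class] with forward/backward committors, reactive
#'   flux and MFPT.
#' @export
transitionPathAnalysis <- function(msm, source, sink) {
  src <- if (is(source, "MacrostateSet")) source else macrostate(source, "source")
  snk <- if (is(sink, "MacrostateSet")) sink else macrostate(sink, "sink")
  q <- committor(msm@T, src@states, snk@states)
  qm <- backwardCommittor(msm@T, msm@pi, src@states, snk@states)
  m <- mfpt(msm, src, snk)
  new("TPTResult", source = src, sink = snk, qPlus = q, qMinus = qm,
      flux = m$flux, mfptFrames = m$frames, mfptNs = m$ns)
}

#' Kinetic Monte Carlo run on an MSM
#'
#' Stochastic state hopping: at each step a uniform R in \[0, 1) is drawn and
#' the chain moves to the state j whose cumulative transition probability
#' interval \[s_{i,j-1}, s_{i,j}) contains R. Each step advances time by the
#' MSM lag. Reproducible given the seed.
#'
#' @param msm a [MarkovStateModel-class].
#' @param startState starting state (position within the active set).
#' @param nSteps number of states in the returned sequence (including the
#'   start).
#' @param seed integer seed.
#' @return a [KmcTrajectory-class].
#' @export
kmcRun <- function(msm, startState, nSteps, seed = 1L) {
  K <- nrow(msm@T)
  if (startState < 1 || startState > K)
    stop("invalid start state: ", startState)
  states <- withSeed(deriveSeed(seed, 0L),
                     sampleStatePath(msm@T, nSteps, startState))
  new("KmcTrajectory", states = as.integer(states),
      stepTimeNs = msm@lag * msm@frameDt, frames = NULL,
      seed = as.integer(seed))
}

#' Stitch trajectory frames onto a kMC state sequence
#'
#' For each kMC step draws one frame uniformly at random from the pool of
#' frames assigned to the visited state, yielding a frame-reference sequence
#' that renders the kMC path as a pseudo-trajectory.
#'
#' @param kmc a [KmcTrajectory-class].
#' @param msm the generating [MarkovStateModel-class] (for the active-set
#'   mapping).
#' @param disc the [Discretization-class] whose assignments define the frame
#'   pools.
#' @param seed integer seed.
#' @return the [KmcTrajectory-class] with a `frames` data.frame (step, state,
#'   trajectory, frame).
#' @export
stitchFrames <- function(kmc, msm, disc, seed = 1L) {
  dtrajs <- if (is(disc, "Discretization")) disc@assignments else disc
  toActive <- rep(NA_integer_, nrow(msm@countMatrix@counts))
  toActive[msm@activeSet] <- seq_along(msm@activeSet)
  pools <- vector("list", length(msm@activeSet))
  for (i in seq_along(dtrajs)) {
    a <- toActive[dtrajs[[i]]]
    for (s in unique(a[!is.na(a)])) {
      idx <- which(a == s)
      pools[[s]] <- rbind(pools[[s]], cbind(i, idx))
    }
  }
  visited <- unique(kmc@states)
  empty <- visited[vapply(visited, function(s) is.null(pools[[s]]), logical(1))]
  if (length(empty))
    stop("no frames assigned to visited state(s): ", paste(empty, collapse = ", "))
  refs <- withSeed(deriveSeed(seed, 0L), {
    t(vapply(kmc@states, function(s) {
      pool <- pools[[s]]
      pool[sample.int(nrow(pool), 1L), ]
    }, numeric(2)))
  })
  kmc@frames <- data.frame(step = seq_along(kmc@states), state = kmc@states,
                           trajectory = as.integer(refs[, 1]),
                           frame = as.integer(refs[, 2]))
  kmc
}

#' Monte-Carlo committor estimate
#'
#' Brute-force oracle: from each requested state, runs `nRuns` independent
#' chain realizations and reports the fraction hitting the sink before the
#' source. Walkers are advanced in parallel by state-grouped multinomial
#' draws.
#'
#' @param T row-stochastic matrix.
#' @param source,sink state sets.
#' @param states states to estimate from (default: all interior states).
#' @param nRuns realizations per state.
#' @param seed integer seed.
#' @param maxSteps safety cap per walker.
#' @return named numeric vector of hit fractions.
#' @export
committorMonteCarlo <- function(T, source, sink, states = NULL, nRuns = 10000L,
                                seed = 1L, maxSteps = 1e6L) {
  A <- .asStates(source); B <- .asStates(sink)
  if (is.null(states)) states <- setdiff(seq_len(nrow(T)), c(A, B))
  withSeed(deriveSeed(seed, 5L), {
    out <- vapply(states, function(s0) {
      cur <- rep.int(s0, nRuns)
      hitB <- logical(nRuns)
      live <- rep(TRUE, nRuns)
      steps <- 0L
      while (any(live) && steps < maxSteps) {
        steps <- steps + 1L
        cur[live] <- stepWalkers(T, cur[live])
        inA <- live & cur %in% A
        inB <- live & cur %in% B
        hitB[inB] <- TRUE
        live[inA | inB] <- FALSE
      }
      mean(hitB)
    }, numeric(1))
    names(out) <- as.character(states)
    out
  })
}

#' Monte-Carlo first-passage time estimate
#'
#' Brute-force oracle for the MFPT: runs `nRuns` walkers started from the
#' source macrostate (start states drawn from the stationary distribution
#' restricted to the source) and reports the mean number of steps to first
#' reach the sink.
#'
#' @param T row-stochastic matrix; @param pi stationary distribution.
#' @param source,sink state sets.
#' @param nRuns walker count.
#' @param seed integer seed.
#' @param maxSteps safety cap.
#' @return mean first-passage time in steps (frames at unit lag).
#' @export
firstPassageMonteCarlo <- function(T, pi, source, sink, nRuns = 10000L,
                                   seed = 1L, maxSteps = 1e7L) {
  A <- .asStates(source); B <- .asStates(sink)
  withSeed(deriveSeed(seed, 6L), {
    p <- pi[A] / sum(pi[A])
    cur <- A[sample.int(length(A), nRuns, replace = TRUE, prob = p)]
    t <- integer(nRuns)
    live <- rep(TRUE, nRuns)
    steps <- 0L
    while (any(live) && steps < maxSteps) {
      steps <- steps + 1L
      cur[live] <- stepWalkers(T, cur[live])
      arrived <- live & cur %in% B
      t[arrived] <- steps
      live[arrived] <- FALSE
    }
    if (any(live)) warning(sum(live), " walkers did not reach the sink within the cap")
    mean(t[!live])
  })
}
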