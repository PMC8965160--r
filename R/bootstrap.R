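## uncertainty module: bootstrap over trajectories with fixed state labels.

## Registry of named statistics. Each entry is function(msm, dtrajs, trajs,
## params) -> numeric scalar or vector.
.statRegistry <- list(
  stationary_distribution = function(msm, dtrajs, trajs, params) {
    full <- rep(0, nrow(msm@countMatrix@counts))
    full[msm@activeSet] <- msm@pi
    full
  },
  state_free_energy = function(msm, dtrajs, trajs, params) {
    temperature <- if (is.null(params$temperature)) 300 else params$temperature
    full <- rep(NA_real_, nrow(msm@countMatrix@counts))
    full[msm@activeSet] <- freeEnergyOfStates(msm@pi, temperature)
    full
  },
  conditional_probability = function(msm, dtrajs, trajs, params) {
    conditionalProbability(msm, dtrajs, trajs, params$condition, params$outcome)
  },
  mfpt = function(msm, dtrajs, trajs, params) {
    mfpt(msm, params$source, params$sink)$ns
  },
  flux = function(msm, dtrajs, trajs, params) {
    reactiveFlux(msm, params$source, params$sink)
  }
)

#' Bootstrap a pipeline statistic over trajectories
#'
#' Each round draws `round(fraction * nTrajs)` trajectories (with replacement
#' in `"resample"` mode, without in `"subsample"` mode), keeps the original
#' discretization labels fixed, re-estimates the MSM on the drawn set at the
#' given lag, and evaluates the statistic. Rounds whose resampled active set
#' breaks the statistic's preconditions (disconnected source/sink,
#' zero-weight condition, ...) are recorded as failures and skipped, not
#' imputed. Per-trajectory count matrices are precomputed once, so MSM
#' re-estimation per round is a cheap matrix sum.
#'
#' For statistics over states of the original discretization
#' ("stationary_distribution", "state_free_energy"), values are reported per
#' original state with 0 / NA outside the round's active set. Macrostates for
#' "mfpt" / "flux" params must be given as original state indices; they are
#' re-mapped into each round's active set (rounds losing a state fail).
#'
#' @param trajs list of [FeatureTrajectory-class] (>= 2).
#' @param disc the fixed [Discretization-class] (or list of assignment
#'   sequences).
#' @param statistic registry name ("stationary_distribution",
#'   "state_free_energy", "conditional_probability", "mfpt", "flux") or a
#'   `function(msm, dtrajs, trajs)` evaluated per round.
#' @param lag MSM lag in frames.
#' @param nRounds bootstrap rounds (default 200).
#' @param fraction trajectory fraction per round (default 0.8).
#' @param mode "resample" (default) or "subsample".
#' @param seed integer seed.
#' @param frameDt nanoseconds per frame.
#' @param params list of statistic parameters (see registry entries).
#' @return a [BootstrapResult-class].
#' @export
bootstrapStatistic <- function(trajs, disc, statistic, lag = 1L,
                               nRounds = 200L, fraction = 0.8,
                               mode = c("resample", "subsample"),
                               seed = 1L, frameDt = 1.0, params = list()) {
  mode <- match.arg(mode)
  dtrajs <- if (is(disc, "Discretization")) disc@assignments else disc
  nT <- length(dtrajs)
  if (nT < 2) stop("bootstrap needs at least 2 trajectories")
  stopifnot(fraction > 0, fraction <= 1)
  nDraw <- max(1L, round(fraction * nT))

  statName <- if (is.character(statistic)) statistic else "custom"
  statFun <- if (is.character(statistic)) {
    if (is.null(.statRegistry[[statistic]]))
      stop("unknown statistic '", statistic, "'; registered: ",
           paste(names(.statRegistry), collapse = ", "))
    .statRegistry[[statistic]]
  } else {
    function(msm, dt, tr, params) statistic(msm, dt, tr)
  }

  ## original-state macrostates get re-mapped per round
  remapStates <- function(msm, orig) {
    pos <- match(orig, msm@activeSet)
    if (anyNA(pos)) stop("macrostate state lost from the bootstrap active set")
    pos
  }

  K <- max(unlist(dtrajs, use.names = FALSE))
  perTrajC <- lapply(dtrajs, function(s) {
    if (length(s) <= lag) return(matrix(0, K, K))
    countTransitions(list(s), lag, nStates = K)@counts
  })

  samples <- list()
  failures <- character(0)
  for (r in seq_len(nRounds)) {
    idx <- withSeed(deriveSeed(seed, r), {
      if (mode == "resample") sample.int(nT, nDraw, replace = TRUE)
      else sample.int(nT, nDraw, replace = FALSE)
    })
    res <- tryCatch({
      Cr <- Reduce(`+`, perTrajC[idx])
      Cobj <- new("CountMatrix", counts = Cr, lag = as.integer(lag),
                  countingMode = "sliding")
      msm <- estimateMSM(Cobj, frameDt)
      p <- params
      if (statName %in% c("mfpt", "flux")) {
        p$source <- remapStates(msm, .asStates(params$source))
        p$sink <- remapStates(msm, .asStates(params$sink))
      }
      statFun(msm, dtrajs[idx], trajs[idx], p)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("round %d: %s", r, conditionMessage(res)))
    } else {
      samples[[length(samples) + 1L]] <- res
    }
  }
  if (!length(samples))
    stop("all bootstrap rounds failed:\n", paste(head(failures, 5), collapse = "\n"))

  M <- do.call(rbind, lapply(samples, as.numeric))
  new("BootstrapResult", statisticName = statName, samples = samples,
      mean = colMeans(M, na.rm = TRUE),
      stdev = apply(M, 2, sd, na.rm = TRUE),
      nRounds = as.integer(nRounds), nFail = length(failures),
      fraction = fraction, mode = mode, seed = as.integer(seed))
}
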