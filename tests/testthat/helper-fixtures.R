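## Shared fixtures, all generated in code.

## MSM with an exactly known transition matrix, via integer counts.
msmFromCounts <- function(C, lag = 1L, frameDt = 1.0) {
  estimateMSM(C, frameDt = frameDt, lag = lag)
}

twoStateMsm <- function(p01 = 0.1, p10 = 0.1, N = 10000L, lag = 1L) {
  C <- rbind(c((1 - p01) * N, p01 * N),
             c(p10 * N, (1 - p10) * N))
  msmFromCounts(round(C), lag = lag)
}

## Batch of trajectories from a preset, one start state per hidden state.
presetTrajectories <- function(system, nTrajs, nSteps, seed = 1L,
                               startFromPi = FALSE) {
  starts <- if (startFromPi) {
    ligandMSM:::withSeed(deriveSeed(seed, 500L),
      sample.int(nStates(system), nTrajs, replace = TRUE,
                 prob = stationaryDistribution(system)))
  } else {
    ((seq_len(nTrajs) - 1L) %% nStates(system)) + 1L
  }
  lapply(seq_len(nTrajs), function(i)
    sampleChainTrajectory(system, nSteps, startState = starts[i],
                          seed = deriveSeed(seed, i)))
}
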