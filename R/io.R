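## cli_io module: trajectory I/O with manifests, result export, config
## validation, and the end-to-end pipeline driver.

#' Write a trajectory set with a manifest
#'
#' Writes one file per trajectory plus a `manifest.json` recording feature
#' names, frame duration, format and per-trajectory metadata. `"rds"` stores
#' compressed binary arrays that round-trip bit-for-bit; `"csv"` writes one
#' row per frame with the feature names as header (plus a `hidden_state`
#' column when the truth is known).
#'
#' @param trajs list of [FeatureTrajectory-class].
#' @param dir output directory (created if missing).
#' @param format "rds" or "csv".
#' @return the manifest path, invisibly.
#' @export
writeTrajectorySet <- function(trajs, dir, format = c("rds", "csv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    file <- sprintf("%s.%s", tr@trajectoryId, format)
    path <- file.path(dir, file)
    if (format == "rds") {
      saveRDS(list(X = tr@X, hiddenStates = tr@hiddenStates), path)
    } else {
      df <- as.data.frame(tr@X)
      colnames(df) <- tr@featureNames
      if (length(tr@hiddenStates)) df$hidden_state <- tr@hiddenStates
      write.csv(df, path, row.names = FALSE)
    }
    list(id = tr@trajectoryId, file = file, nFrames = nrow(tr@X))
  })
  manifest <- list(featureNames = trajs[[1]]@featureNames,
                   frameDt = trajs[[1]]@frameDt,
                   format = format, trajectories = entries)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mpath)
}

#' Load a trajectory set
#'
#' Reads a directory written by [writeTrajectorySet()] (or a manifest path
#' directly). Feature sets must be consistent across files; a CSV missing a
#' manifest feature column is a schema error naming the column, and
#' non-numeric cells are rejected.
#'
#' @param path directory containing `manifest.json`, or the manifest path.
#' @return list of [FeatureTrajectory-class].
#' @export
loadTrajectories <- function(path) {
  mpath <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  if (!file.exists(mpath)) {
    if (dir.exists(path) && !length(list.files(path)))
      stop("empty input directory: ", path)
    stop("no manifest found at ", mpath)
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  fn <- manifest$featureNames
  dir <- dirname(mpath)
  entries <- manifest$trajectories
  lapply(seq_len(nrow(entries)), function(i) {
    file <- file.path(dir, entries$file[i])
    ext <- tolower(tools::file_ext(file))
    if (ext == "rds") {
      payload <- readRDS(file)
      X <- payload$X
      hid <- as.integer(payload$hiddenStates)
      if (ncol(X) != length(fn))
        stop("feature set mismatch in ", entries$file[i])
    } else if (ext == "csv") {
      df <- read.csv(file, check.names = FALSE)
      missing <- setdiff(fn, colnames(df))
      if (length(missing))
        stop("missing feature column(s) in ", entries$file[i], ": ",
             paste(missing, collapse = ", "))
      X <- as.matrix(df[, fn, drop = FALSE])
      if (!is.numeric(X)) stop("non-numeric feature cells in ", entries$file[i])
      hid <- if ("hidden_state" %in% colnames(df))
        as.integer(df$hidden_state) else integer(0)
    } else stop("unsupported trajectory format: ", ext)
    colnames(X) <- fn
    new("FeatureTrajectory", trajectoryId = entries$id[i],
        frameDt = manifest$frameDt, X = X, featureNames = fn,
        hiddenStates = hid)
  })
}

#' Export a free-energy surface as a CSV grid
#'
#' @param surface a [FreeEnergySurface-class].
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
exportLandscapeCSV <- function(surface, path) {
  xm <- (surface@xEdges[-1] + surface@xEdges[-length(surface@xEdges)]) / 2
  if (length(surface@yEdges)) {
    ym <- (surface@yEdges[-1] + surface@yEdges[-length(surface@yEdges)]) / 2
    grid <- expand.grid(x = xm, y = ym)
    grid$G <- as.vector(surface@G)
  } else {
    grid <- data.frame(x = xm, G = surface@G)
  }
  write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' Export a TPT result as JSON
#'
#' @param tpt a [TPTResult-class].
#' @param path output JSON.
#' @return the path, invisibly.
#' @export
exportTPTJson <- function(tpt, path) {
  jsonlite::write_json(list(
    source = tpt@source@name, sink = tpt@sink@name,
    sourceStates = tpt@source@states, sinkStates = tpt@sink@states,
    qPlus = tpt@qPlus, qMinus = tpt@qMinus,
    fluxPerLag = tpt@flux,
    mfptFrames = tpt@mfptFrames, mfptNs = tpt@mfptNs,
    units = list(flux = "per lag step", mfpt = c("frames", "ns"))
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

## Config schema: known blocks and keys; unknown keys are rejected.
.configSchema <- list(
  scenario = c("name", "seed", "nTrajectories", "nSteps", "adaptive",
               "nRounds", "trajsPerRound", "stepsPerTraj", "nClusters"),
  featurization = c("ticaLag", "varianceFraction", "K", "maxIter", "nRestarts"),
  msm = c("lag", "mode", "temperature"),
  landscape = c("x", "y", "bins"),
  kinetics = c("kmcSteps", "source", "sink", "nTop"),
  bootstrap = c("rounds", "fraction", "mode")
)

#' Validate a pipeline configuration
#'
#' Checks block and key names against the schema (unknown keys are rejected)
#' and fills defaults. Accepts a nested list or a YAML/JSON file path.
#'
#' @param config nested list, or path to a YAML/JSON file.
#' @return the validated, default-filled config list.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("[.]ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  unknownBlocks <- setdiff(names(config), names(.configSchema))
  if (length(unknownBlocks))
    stop("unknown config block(s): ", paste(unknownBlocks, collapse = ", "))
  for (b in names(config)) {
    unknown <- setdiff(names(config[[b]]), .configSchema[[b]])
    if (length(unknown))
      stop("unknown key(s) in block '", b, "': ", paste(unknown, collapse = ", "))
  }
  defaults <- list(
    scenario = list(name = "binding_landscape", seed = 1L, nTrajectories = 20L,
                    nSteps = 2000L, adaptive = FALSE, nRounds = 5L,
                    trajsPerRound = 4L, stepsPerTraj = 500L, nClusters = 10L),
    featurization = list(ticaLag = 5L, varianceFraction = 0.9, K = 20L,
                         maxIter = 50L, nRestarts = 3L),
    msm = list(lag = 5L, mode = "sliding", temperature = 300),
    landscape = list(x = "binding_distance", y = NULL, bins = 40L),
    kinetics = list(kmcSteps = 2000L, source = "unbound", sink = "agonist",
                    nTop = 5L),
    bootstrap = list(rounds = 50L, fraction = 0.8, mode = "resample")
  )
  for (b in names(defaults)) {
    block <- if (is.null(config[[b]])) list() else config[[b]]
    for (k in names(defaults[[b]]))
      if (is.null(block[[k]])) block[[k]] <- defaults[[b]][[k]]
    config[[b]] <- block
  }
  config
}

## Stable hash of a config: md5 of its canonical JSON rendering.
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes the stages end-to-end on a synthetic scenario: simulate (direct
#' chain sampling or least-counts adaptive sampling) -> TICA -> k-means ->
#' MSM -> weighted landscape -> macrostates and TPT -> kinetic Monte Carlo ->
#' bootstrap. Writes all artifacts plus a machine-readable `summary.json`
#' (carrying the config, its hash and the seed) and a run log under
#' `outDir`. Stage failures abort with stage-named diagnostics. Identical
#' configs give identical summaries.
#'
#' @param config nested config list or YAML/JSON path (see
#'   [validateConfig()]).
#' @param outDir output directory.
#' @return the summary list, invisibly.
#' @export
runPipeline <- function(config, outDir = tempfile("ligandmsm_run_")) {
  config <- validateConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "run.log")
  logLine <- function(stage, text) {
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%H:%M:%S"), stage, text),
        file = logPath, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logLine(name, sprintf("done in %.2fs", as.numeric(Sys.time() - t0, "secs")))
    res
  }
  summary <- list(configHash = configHash(config), config = config,
                  package = as.character(utils::packageVersion("ligandMSM")))
  sc <- config$scenario; fz <- config$featurization
  mc <- config$msm; kin <- config$kinetics; bs <- config$bootstrap

  system <- stage("system", buildGroundTruthChain(sc$name, seed = sc$seed))
  trajs <- stage("simulate", {
    if (isTRUE(sc$adaptive)) {
      runAdaptiveSampling(system, sc$nRounds, sc$trajsPerRound,
                          sc$stepsPerTraj, sc$nClusters, seed = sc$seed)
    } else {
      lapply(seq_len(sc$nTrajectories), function(i)
        sampleChainTrajectory(system, sc$nSteps,
                              startState = ((i - 1L) %% system@nStates) + 1L,
                              seed = deriveSeed(sc$seed, i),
                              trajectoryId = sprintf("traj%03d", i)))
    }
  })
  writeTrajectorySet(trajs, file.path(outDir, "trajectories"), format = "csv")

  tica <- stage("tica", fitTica(trajs, lag = fz$ticaLag,
                                varianceFraction = fz$varianceFraction))
  tics <- ticaTransform(tica, trajs)
  disc <- stage("cluster", kmeansDiscretize(tics, K = fz$K, seed = sc$seed,
                                            maxIter = fz$maxIter,
                                            nRestarts = fz$nRestarts))
  msm <- stage("msm", estimateMSM(
    countTransitions(disc, mc$lag, mc$mode), frameDt = system@frameDt))
  summary$msm <- list(nActive = nrow(msm@T), lagFrames = msm@lag,
                      piRange = range(msm@pi),
                      vamp2 = vamp2Score(disc, mc$lag, nProcesses = 5L))

  surface <- stage("landscape", weightedLandscape(
    msm, disc, trajs, obsX = config$landscape$x, obsY = config$landscape$y,
    bins = config$landscape$bins, temperature = mc$temperature))
  exportLandscapeCSV(surface, file.path(outDir, "landscape.csv"))

  ## macrostates: map clusters to hidden macrostates by majority vote
  map <- majorityVoteMap(disc, trajs)
  macroOf <- function(label) {
    hid <- system@macrostateLabels[[label]]
    if (is.null(hid)) stop("unknown macrostate label: ", label)
    pos <- which(map[msm@activeSet] %in% hid)
    if (!length(pos)) stop("macrostate '", label, "' has no active states")
    macrostate(pos, label)
  }
  tpt <- stage("tpt", transitionPathAnalysis(msm, macroOf(kin$source),
                                             macroOf(kin$sink)))
  exportTPTJson(tpt, file.path(outDir, "tpt.json"))
  summary$tpt <- list(source = kin$source, sink = kin$sink,
                      fluxPerLag = tpt@flux, mfptNs = tpt@mfptNs)

  if (kin$kmcSteps > 0) {
    kmc <- stage("kmc", {
      start <- macroOf(kin$source)@states[1]
      k <- kmcRun(msm, start, kin$kmcSteps, seed = deriveSeed(sc$seed, 77L))
      stitchFrames(k, msm, disc, seed = deriveSeed(sc$seed, 78L))
    })
    write.csv(cbind(kmc@frames,
                    time_ns = (kmc@frames$step - 1L) * kmc@stepTimeNs),
              file.path(outDir, "kmc.csv"), row.names = FALSE)
    summary$kmc <- list(steps = kin$kmcSteps, stepTimeNs = kmc@stepTimeNs)
  } else {
    summary$kmc <- "skipped (kmcSteps = 0)"
  }

  boot <- stage("bootstrap", bootstrapStatistic(
    trajs, disc, "stationary_distribution", lag = mc$lag,
    nRounds = bs$rounds, fraction = bs$fraction, mode = bs$mode,
    seed = deriveSeed(sc$seed, 99L), frameDt = system@frameDt))
  summary$bootstrap <- list(rounds = bs$rounds, nFail = boot@nFail,
                            maxPiStdev = max(boot@stdev))

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logLine("pipeline", "complete")
  invisible(summary)
}
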