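#' @title Accessor generics
#' @description Accessors for the core S4 containers: transition matrix,
#'   stationary distribution, active set, lag time, state/frame counts and
#'   trajectory matrices. Use these rather than reaching into slots.
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))

#' @rdname accessors
#' @export
setGeneric("stationaryDistribution", function(object) standardGeneric("stationaryDistribution"))

#' @rdname accessors
#' @export
setGeneric("activeSet", function(object) standardGeneric("activeSet"))

#' @rdname accessors
#' @export
setGeneric("lagFrames", function(object) standardGeneric("lagFrames"))

#' @rdname accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("trajectoryMatrix", function(object) standardGeneric("trajectoryMatrix"))

#' @rdname accessors
#' @export
setGeneric("hiddenStates", function(object) standardGeneric("hiddenStates"))

#' @rdname accessors
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(object) standardGeneric("clusterCenters"))

#' @rdname accessors
#' @export
setGeneric("countMatrix", function(object) standardGeneric("countMatrix"))

#' @rdname accessors
#' @export
setGeneric("frameDt", function(object) standardGeneric("frameDt"))

setMethod("transitionMatrix", "MarkovStateModel", function(object) object@T)
setMethod("transitionMatrix", "GroundTruthSystem", function(object) object@Ttrue)
setMethod("stationaryDistribution", "MarkovStateModel", function(object) object@pi)
setMethod("stationaryDistribution", "GroundTruthSystem", function(object) object@piTrue)
setMethod("activeSet", "MarkovStateModel", function(object) object@activeSet)
setMethod("lagFrames", "MarkovStateModel", function(object) object@lag)
setMethod("lagFrames", "CountMatrix", function(object) object@lag)
setMethod("lagFrames", "TicaModel", function(object) object@lag)
setMethod("nStates", "MarkovStateModel", function(object) nrow(object@T))
setMethod("nStates", "GroundTruthSystem", function(object) object@nStates)
setMethod("nFrames", "FeatureTrajectory", function(object) nrow(object@X))
setMethod("featureNames", "FeatureTrajectory", function(object) object@featureNames)
setMethod("featureNames", "EnsembleMatrix", function(object) object@featureNames)
setMethod("trajectoryMatrix", "FeatureTrajectory", function(object) object@X)
setMethod("hiddenStates", "FeatureTrajectory", function(object) object@hiddenStates)
setMethod("assignments", "Discretization", function(object) object@assignments)
setMethod("clusterCenters", "Discretization", function(object) object@centers)
setMethod("countMatrix", "MarkovStateModel", function(object) object@countMatrix)
setMethod("frameDt", "MarkovStateModel", function(object) object@frameDt)
setMethod("frameDt", "FeatureTrajectory", function(object) object@frameDt)
setMethod("frameDt", "GroundTruthSystem", function(object) object@frameDt)

setMethod("show", "GroundTruthSystem", function(object) {
  cat("GroundTruthSystem '", object@scenario, "': ", object@nStates,
      " hidden states, ", length(object@featureNames), " features (",
      paste(object@featureNames, collapse = ", "), ")\n", sep = "")
  cat("  frameDt:", object@frameDt, "ns; macrostates:",
      paste(names(object@macrostateLabels), collapse = ", "), "\n")
})

setMethod("show", "FeatureTrajectory", function(object) {
  cat("FeatureTrajectory '", object@trajectoryId, "': ", nrow(object@X),
      " frames x ", ncol(object@X), " features, dt = ", object@frameDt,
      " ns", if (length(object@hiddenStates)) " (hidden states known)", "\n",
      sep = "")
})

setMethod("show", "TicaModel", function(object) {
  cat("TicaModel: lag", object@lag, "frames,", ncol(object@components),
      "components retained,", sprintf("%.1f%%", 100 * object@kineticVarianceFraction),
      "kinetic variance\n")
  cat("  leading eigenvalues:",
      paste(sprintf("%.4f", head(object@eigenvalues, 5)), collapse = ", "), "\n")
})

setMethod("show", "Discretization", function(object) {
  cat("Discretization: K =", object@K, "clusters over",
      sum(lengths(object@assignments)), "frames in",
      length(object@assignments), "trajectories\n")
})

setMethod("show", "MarkovStateModel", function(object) {
  cat("MarkovStateModel:", nrow(object@T), "active states (of",
      nrow(object@countMatrix@counts), "), lag", object@lag, "frames (",
      object@lag * object@frameDt, "ns )\n")
  cat("  pi range: [", sprintf("%.3g", min(object@pi)), ",",
      sprintf("%.3g", max(object@pi)), "]\n")
})

setMethod("show", "TPTResult", function(object) {
  cat("TPTResult ", object@source@name, " -> ", object@sink@name,
      ": flux ", sprintf("%.4g", object@flux), " per lag, MFPT ",
      sprintf("%.4g", object@mfptFrames), " frames (",
      sprintf("%.4g", object@mfptNs), " ns)\n", sep = "")
})

setMethod("show", "MutualInfoNetwork", function(object) {
  cat("MutualInfoNetwork:", object@nResidues, "residues,",
      nrow(object@edges), "edges (distance <", object@distanceCutoff, "A)\n")
})

setMethod("show", "BootstrapResult", function(object) {
  cat("BootstrapResult '", object@statisticName, "': ",
      length(object@samples), " successful rounds (", object@nFail,
      " failed) of ", object@nRounds, "; mode ", object@mode, ", fraction ",
      object@fraction, "\n", sep = "")
  if (length(object@mean) <= 6) {
    cat("  mean:", sprintf("%.4g", object@mean),
        "\n  stdev:", sprintf("%.4g", object@stdev), "\n")
  }
})
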