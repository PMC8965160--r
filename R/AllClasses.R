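#' @import methods
#' @importFrom stats kmeans prcomp rnorm runif sd quantile binom.test setNames
#' @importFrom utils head read.csv write.csv
NULL

## Boltzmann constant in kcal/mol/K, the unit system used throughout.
.kB <- 0.0019872

#' Ground-truth Markov chain with Gaussian feature emissions
#'
#' Defines a hidden metastable-state chain (row-stochastic transition matrix,
#' stationary distribution) together with a per-state diagonal-covariance
#' Gaussian emission model over named molecular features (distances in
#' Angstrom, angles in degrees). Serves as the generative oracle against which
#' every downstream stage of the pipeline can be validated.
#'
#' @slot nStates number of hidden metastable states.
#' @slot Ttrue row-stochastic transition matrix (nStates x nStates) at unit lag.
#' @slot piTrue stationary distribution of `Ttrue`.
#' @slot emissionMeans nStates x F matrix of feature means per state.
#' @slot emissionSds nStates x F matrix of positive feature standard deviations.
#' @slot featureNames character vector of F feature labels.
#' @slot macrostateLabels named list mapping macrostate name -> hidden state
#'   indices (disjoint sets).
#' @slot frameDt time per frame in nanoseconds.
#' @slot scenario preset name ("two_state", "double_well_1d",
#'   "binding_landscape", "bottleneck_chain", "custom", ...).
#' @slot params list of scenario parameters (e.g. the configured basin
#'   free-energy gap of the double-well preset).
#' @export
setClass("GroundTruthSystem",
  slots = c(
    nStates = "integer",
    Ttrue = "matrix",
    piTrue = "numeric",
    emissionMeans = "matrix",
    emissionSds = "matrix",
    featureNames = "character",
    macrostateLabels = "list",
    frameDt = "numeric",
    scenario = "character",
    params = "list"
  )
)

setValidity("GroundTruthSystem", function(object) {
  msg <- character()
  n <- object@nStates
  T <- object@Ttrue
  if (nrow(T) != n || ncol(T) != n) msg <- c(msg, "Ttrue must be nStates x nStates")
  if (any(T < 0)) msg <- c(msg, "Ttrue entries must be non-negative")
  if (any(abs(rowSums(T) - 1) > 1e-12)) msg <- c(msg, "rows of Ttrue must sum to 1 within 1e-12")
  if (length(object@piTrue) != n) msg <- c(msg, "piTrue length must equal nStates")
  if (max(abs(drop(object@piTrue %*% T) - object@piTrue)) > 1e-10)
    msg <- c(msg, "piTrue must be a left fixed point of Ttrue within 1e-10")
  if (any(object@emissionSds <= 0)) msg <- c(msg, "emissionSds must be positive")
  if (nrow(object@emissionMeans) != n || nrow(object@emissionSds) != n)
    msg <- c(msg, "emission matrices must have nStates rows")
  if (length(object@featureNames) != ncol(object@emissionMeans))
    msg <- c(msg, "featureNames length must equal number of features")
  states <- unlist(object@macrostateLabels, use.names = FALSE)
  if (anyDuplicated(states)) msg <- c(msg, "macrostate sets must be disjoint")
  if (length(states) && (any(states < 1) || any(states > n)))
    msg <- c(msg, "macrostate state indices out of range")
  if (object@frameDt <= 0) msg <- c(msg, "frameDt must be positive")
  if (length(msg)) msg else TRUE
})

#' Feature trajectory
#'
#' One trajectory's frames x features matrix of molecular observables, with
#' labelled features and the frame duration. Synthetic trajectories also carry
#' the true hidden-state path used for recovery tests.
#'
#' @slot trajectoryId character identifier.
#' @slot frameDt nanoseconds per frame.
#' @slot X frames x F numeric matrix of feature values.
#' @slot featureNames F feature labels.
#' @slot hiddenStates integer per-frame true state index (length 0 when
#'   unknown, as for real data).
#' @export
setClass("FeatureTrajectory",
  slots = c(
    trajectoryId = "character",
    frameDt = "numeric",
    X = "matrix",
    featureNames = "character",
    hiddenStates = "integer"
  )
)

setValidity("FeatureTrajectory", function(object) {
  msg <- character()
  if (nrow(object@X) < 2) msg <- c(msg, "a trajectory needs at least 2 frames")
  if (!all(is.finite(object@X))) msg <- c(msg, "all feature values must be finite")
  if (length(object@featureNames) != ncol(object@X))
    msg <- c(msg, "featureNames length must equal number of feature columns")
  if (length(object@hiddenStates) && length(object@hiddenStates) != nrow(object@X))
    msg <- c(msg, "hiddenStates must align with frames")
  if (object@frameDt <= 0) msg <- c(msg, "frameDt must be positive")
  if (length(msg)) msg else TRUE
})

#' Dihedral ensemble with planted coupling chain
#'
#' Per-residue dihedral time series (degrees, in \[-180, 180)) plus a residue
#' contact-distance map and the ground-truth coupled-residue path, used as the
#' fixture for mutual-information allosteric network analysis.
#'
#' @slot label condition label (e.g. "agonist_like").
#' @slot nResidues residue count.
#' @slot D frames x nResidues matrix of dihedral angles in degrees.
#' @slot contactDistances symmetric nResidues x nResidues distance matrix (A).
#' @slot plantedPath ordered residue indices of the true coupling chain.
#' @export
setClass("DihedralEnsemble",
  slots = c(
    label = "character",
    nResidues = "integer",
    D = "matrix",
    contactDistances = "matrix",
    plantedPath = "integer"
  )
)

setValidity("DihedralEnsemble", function(object) {
  msg <- character()
  cd <- object@contactDistances
  if (ncol(object@D) != object@nResidues) msg <- c(msg, "D must have nResidues columns")
  if (!isTRUE(all.equal(cd, t(cd), tolerance = 1e-10)))
    msg <- c(msg, "contactDistances must be symmetric")
  if (any(abs(diag(cd)) > 1e-12)) msg <- c(msg, "contactDistances diagonal must be zero")
  if (any(object@D < -180 - 1e-9) || any(object@D >= 180 + 1e-9))
    msg <- c(msg, "angles must lie in [-180, 180)")
  if (length(msg)) msg else TRUE
})

#' TICA model
#'
#' Linear transform onto time-lagged independent components: the generalized
#' eigenvectors of the symmetrized time-lagged covariance against the
#' (regularized) instantaneous covariance.
#'
#' @slot lag lag in frames.
#' @slot mean F-vector removed before the eigenproblem.
#' @slot eigenvalues all generalized eigenvalues, sorted descending.
#' @slot components F x k matrix of retained components (orthonormal under the
#'   instantaneous covariance).
#' @slot kineticVarianceFraction fraction of total kinetic variance (sum of
#'   squared eigenvalues) achieved by the retained components.
#' @slot requestedFraction the requested fraction.
#' @export
setClass("TicaModel",
  slots = c(
    lag = "integer",
    mean = "numeric",
    eigenvalues = "numeric",
    components = "matrix",
    kineticVarianceFraction = "numeric",
    requestedFraction = "numeric"
  )
)

setValidity("TicaModel", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (is.unsorted(rev(ev), strictly = FALSE)) msg <- c(msg, "eigenvalues must be sorted descending")
  if (any(abs(ev) > 1 + 1e-6)) msg <- c(msg, "|eigenvalue| must be <= 1 + tolerance")
  if (length(msg)) msg else TRUE
})

#' k-means discretization
#'
#' Cluster centers and per-trajectory integer assignment sequences; every frame
#' is assigned to its nearest center in Euclidean distance.
#'
#' @slot centers K x d matrix of cluster centers.
#' @slot assignments list of integer vectors, one per trajectory, aligned 1:1
#'   with the input frames.
#' @slot K cluster count.
#' @slot seed integer seed the discretization was produced under.
#' @slot inertia total within-cluster sum of squares.
#' @export
setClass("Discretization",
  slots = c(
    centers = "matrix",
    assignments = "list",
    K = "integer",
    seed = "integer",
    inertia = "numeric"
  )
)

#' Transition count matrix
#'
#' @slot counts K x K matrix of observed (i at t, j at t+lag) pair counts.
#' @slot lag lag in frames.
#' @slot countingMode "sliding" (all t) or "strided" (t = 0, lag, 2 lag, ...).
#' @export
setClass("CountMatrix",
  slots = c(counts = "matrix", lag = "integer", countingMode = "character")
)

setValidity("CountMatrix", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (max(abs(object@counts - round(object@counts))) > 1e-9) msg <- c(msg, "counts must be integers")
  if (!object@countingMode %in% c("sliding", "strided"))
    msg <- c(msg, "countingMode must be 'sliding' or 'strided'")
  if (length(msg)) msg else TRUE
})

#' Markov state model
#'
#' Row-stochastic transition matrix over the largest strongly connected set of
#' the count graph (the active set), its stationary distribution, and the
#' generating counts.
#'
#' @slot T row-stochastic transition matrix over the active set.
#' @slot pi stationary distribution (leading left eigenvector, sums to 1).
#' @slot activeSet original state indices retained, ascending.
#' @slot lag lag in frames.
#' @slot frameDt nanoseconds per frame.
#' @slot countMatrix the generating [CountMatrix-class].
#' @export
setClass("MarkovStateModel",
  slots = c(
    T = "matrix",
    pi = "numeric",
    activeSet = "integer",
    lag = "integer",
    frameDt = "numeric",
    countMatrix = "CountMatrix"
  )
)

setValidity("MarkovStateModel", function(object) {
  msg <- character()
  T <- object@T
  if (any(abs(rowSums(T) - 1) > 1e-12)) msg <- c(msg, "rows of T must sum to 1 within 1e-12")
  if (any(object@pi < -1e-12)) msg <- c(msg, "pi must be non-negative")
  if (abs(sum(object@pi) - 1) > 1e-10) msg <- c(msg, "pi must sum to 1")
  if (max(abs(drop(object@pi %*% T) - object@pi)) > 1e-10)
    msg <- c(msg, "pi must satisfy pi T = pi within 1e-10")
  if (anyDuplicated(object@activeSet)) msg <- c(msg, "activeSet indices must be unique")
  if (length(object@activeSet) != nrow(T)) msg <- c(msg, "activeSet must match T dimension")
  if (length(msg)) msg else TRUE
})

#' Free-energy surface
#'
#' Binned MSM-weighted free energies over one or two observables, in kcal/mol,
#' shifted so the global minimum over populated bins is 0. Bins with zero
#' weight are masked (NA).
#'
#' @slot xEdges,yEdges bin boundaries in observable units (`yEdges` empty for a
#'   1-D profile).
#' @slot G vector (1-D) or matrix (2-D) of free energies.
#' @slot mask logical, TRUE where the bin carries no weight.
#' @slot temperature Kelvin.
#' @export
setClass("FreeEnergySurface",
  slots = c(
    xEdges = "numeric", yEdges = "numeric",
    G = "ANY", mask = "ANY", temperature = "numeric"
  )
)

#' Macrostate: a named set of MSM states
#'
#' @slot name label.
#' @slot states positions within the MSM active set.
#' @slot definition human-readable record of the region predicate and
#'   selection rule.
#' @export
setClass("MacrostateSet",
  slots = c(name = "character", states = "integer", definition = "character")
)

#' Transition-path-theory result
#'
#' @slot source,sink the two [MacrostateSet-class]s.
#' @slot qPlus forward committor per active state (0 on source, 1 on sink).
#' @slot qMinus backward committor per active state.
#' @slot flux reactive flux F_AB per lag step.
#' @slot mfptFrames mean first-passage time tau * pi_A / F_AB in frames.
#' @slot mfptNs the same in nanoseconds.
#' @export
setClass("TPTResult",
  slots = c(
    source = "MacrostateSet", sink = "MacrostateSet",
    qPlus = "numeric", qMinus = "numeric",
    flux = "numeric", mfptFrames = "numeric", mfptNs = "numeric"
  )
)

setValidity("TPTResult", function(object) {
  msg <- character()
  q <- object@qPlus
  if (any(q < -1e-9) || any(q > 1 + 1e-9)) msg <- c(msg, "committor must lie in [0, 1]")
  if (max(abs(q[object@source@states])) > 1e-9) msg <- c(msg, "committor must be 0 on source")
  if (max(abs(q[object@sink@states] - 1)) > 1e-9) msg <- c(msg, "committor must be 1 on sink")
  if (object@flux < 0) msg <- c(msg, "flux must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Kinetic Monte Carlo trajectory
#'
#' @slot states integer state sequence (positions within the MSM active set).
#' @slot stepTimeNs time advanced per step: MSM lag x frameDt.
#' @slot frames optional stitched frame references (data.frame with step,
#'   state, trajectory, frame), or NULL.
#' @slot seed seed used.
#' @export
setClass("KmcTrajectory",
  slots = c(states = "integer", stepTimeNs = "numeric", frames = "ANY", seed = "integer")
)

#' Mutual-information allosteric network
#'
#' Residue graph whose edges require both spatial contact (distance below a
#' cutoff) and statistical coupling (normalized mutual information above a
#' threshold); edge path-cost is -ln(nMI) clipped at a ceiling.
#'
#' @slot nResidues residue count.
#' @slot mi symmetric matrix of normalized mutual information in \[0, 1\].
#' @slot contactDistances symmetric distance matrix (A).
#' @slot edges data.frame (i, j, distance, nmi, cost) of gated edges.
#' @slot graph the igraph object used for shortest paths.
#' @slot distanceCutoff,miThreshold the gates applied.
#' @export
setClass("MutualInfoNetwork",
  slots = c(
    nResidues = "integer", mi = "matrix", contactDistances = "matrix",
    edges = "data.frame", graph = "ANY",
    distanceCutoff = "numeric", miThreshold = "ANY"
  )
)

#' Ensemble feature matrix
#'
#' @slot label condition label.
#' @slot X frames x P feature matrix.
#' @slot featureNames P labels.
#' @slot featureResidues named list mapping feature -> involved residue
#'   indices (length 1 or 2).
#' @export
setClass("EnsembleMatrix",
  slots = c(
    label = "character", X = "matrix",
    featureNames = "character", featureResidues = "list"
  )
)

setValidity("EnsembleMatrix", function(object) {
  msg <- character()
  if (!all(is.finite(object@X))) msg <- c(msg, "feature values must be finite")
  if (length(object@featureNames) != ncol(object@X))
    msg <- c(msg, "featureNames must match columns")
  if (!all(object@featureNames %in% names(object@featureResidues)))
    msg <- c(msg, "featureResidues must cover all features")
  if (length(msg)) msg else TRUE
})

#' Bootstrap result
#'
#' @slot statisticName label of the re-estimated statistic.
#' @slot samples list of per-round values (scalars or vectors).
#' @slot mean,stdev element-wise mean and standard deviation over successful
#'   rounds.
#' @slot nRounds rounds requested; @slot nFail rounds that failed the
#'   statistic's preconditions (recorded, not imputed).
#' @slot fraction trajectory fraction drawn per round.
#' @slot mode "resample" (with replacement) or "subsample" (without).
#' @slot seed integer seed.
#' @export
setClass("BootstrapResult",
  slots = c(
    statisticName = "character", samples = "list",
    mean = "numeric", stdev = "numeric",
    nRounds = "integer", nFail = "integer",
    fraction = "numeric", mode = "character", seed = "integer"
  )
)
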