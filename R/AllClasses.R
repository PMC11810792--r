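#' @import methods
#' @importFrom stats quantile sd cor fft ks.test t.test wilcox.test kmeans
#'   rnorm runif rexp rbinom lm coef pt approx median var mvfft convolve
#'   setNames complete.cases p.adjust
#' @importFrom utils head tail write.csv read.csv
#' @importFrom graphics hist
#' @importFrom Rcpp sourceCpp
#' @useDynLib calciumvr, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## Central S4 containers
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic virtual-reality session and chessboard-scan
#' imaging generator.  Defaults emulate the experimental conditions of the
#' fast visual-learning task: ~97 recorded somata, ~14.31 Hz per-cell frame
#' rate, 3-ms treadmill sampling, a 3.5-s grace period in the aversive zone
#' followed by 0.4-s airpuff pulses every 0.8 s, teleports on average every
#' 20 s, and forced teleports after 8 s of immobility.
#'
#' @slot seed integer RNG seed.
#' @slot nNeurons number of somata.
#' @slot imagingRate per-cell imaging rate (Hz).
#' @slot behaviorDt treadmill sampling step (s).
#' @slot nTrialsPerZone grating-zone visits per zone type.
#' @slot zones zone labels; first must be the aversive zone.
#' @slot zoneGrace grace period before the first airpuff (s).
#' @slot puffDuration airpuff pulse length (s).
#' @slot puffPeriod airpuff pulse period (s).
#' @slot immobilityTimeout immobility before a forced teleport (s).
#' @slot meanInterteleport mean neutral-corridor interval between zone
#'   visits (s).
#' @slot noiseSd additive trace noise (dF/F units).
#' @slot neuropilMix neuropil contamination fraction in soma pixels.
#' @slot gridShape chessboard grid (rows, cols).
#' @slot subfieldSize subfield pixel size (h, w).
#' @slot hubFraction fraction of neurons that are hub cells.
#' @slot rampDuration ramp onset time before the zone end (s).
#' @slot baselineVelocity mean running speed (cm/s).
#' @slot velocitySd slow fluctuation SD of running speed (cm/s).
#' @slot pImmobile probability that a neutral period freezes into immobility.
#' @slot fillValue value marking uncovered pixels after registration (0 or NaN).
#' @exportClass SimConfig
setClass("SimConfig", representation(
  seed = "integer", nNeurons = "integer", imagingRate = "numeric",
  behaviorDt = "numeric", nTrialsPerZone = "integer", zones = "character",
  zoneGrace = "numeric", puffDuration = "numeric", puffPeriod = "numeric",
  immobilityTimeout = "numeric", meanInterteleport = "numeric",
  noiseSd = "numeric", neuropilMix = "numeric", gridShape = "integer",
  subfieldSize = "integer", hubFraction = "numeric", rampDuration = "numeric",
  baselineVelocity = "numeric", velocitySd = "numeric", pImmobile = "numeric",
  fillValue = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  pos <- c(imagingRate = object@imagingRate, behaviorDt = object@behaviorDt,
           zoneGrace = object@zoneGrace, puffDuration = object@puffDuration,
           puffPeriod = object@puffPeriod,
           immobilityTimeout = object@immobilityTimeout,
           meanInterteleport = object@meanInterteleport,
           rampDuration = object@rampDuration)
  for (nm in names(pos)) {
    if (!is.finite(pos[[nm]]) || pos[[nm]] <= 0)
      msg <- c(msg, sprintf("'%s' must be finite and > 0", nm))
  }
  for (nm in c("noiseSd", "baselineVelocity", "velocitySd")) {
    v <- slot(object, nm)
    if (!is.finite(v)) msg <- c(msg, sprintf("'%s' must be finite", nm))
  }
  for (nm in c("neuropilMix", "hubFraction", "pImmobile")) {
    v <- slot(object, nm)
    if (!is.finite(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("'%s' must lie in [0, 1]", nm))
  }
  if (object@nNeurons < 1L) msg <- c(msg, "'nNeurons' must be >= 1")
  if (object@nTrialsPerZone < 1L) msg <- c(msg, "'nTrialsPerZone' must be >= 1")
  if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
    msg <- c(msg, "'gridShape' must be two positive integers")
  if (prod(object@gridShape) < object@nNeurons)
    msg <- c(msg, "'gridShape' rows x cols must be >= nNeurons (one soma per subfield)")
  if (length(object@zones) < 2L)
    msg <- c(msg, "need at least one aversive and one control zone")
  if (length(msg)) msg else TRUE
})

#' Session event and velocity log
#'
#' Timestamped zone / airpuff / lick / teleport events plus the treadmill
#' velocity trace sampled every `behaviorDt` seconds (negative velocity
#' allowed), and a per-trial summary table.
#'
#' @slot events data.frame with columns `time`, `kind`, `zone`.
#' @slot velocity data.frame with columns `time`, `velocity`, `position`.
#' @slot behaviorDt sampling step of the velocity trace (s).
#' @slot duration session length (s).
#' @slot trials per-trial summary: entry/exit times, zone, scheduled first
#'   airpuff time, number of pulses delivered, escape flag.
#' @slot zoneGrace grace period used when the log was generated (s).
#' @exportClass SessionLog
setClass("SessionLog", representation(
  events = "data.frame", velocity = "data.frame", behaviorDt = "numeric",
  duration = "numeric", trials = "data.frame", zoneGrace = "numeric"))

setValidity("SessionLog", function(object) {
  msg <- character()
  ev <- object@events
  if (!all(c("time", "kind", "zone") %in% names(ev)))
    msg <- c(msg, "events must have columns time, kind, zone")
  else if (nrow(ev) > 1L && is.unsorted(ev$time))
    msg <- c(msg, "events must be time-sorted")
  if (!all(c("time", "velocity", "position") %in% names(object@velocity)))
    msg <- c(msg, "velocity must have columns time, velocity, position")
  if (length(msg)) msg else TRUE
})

#' Chessboard-scan movie
#'
#' Per-subfield frame stacks from the 3D chessboard scanning mode: each
#' recorded soma has a small subfield scanned around it at an arbitrary 3D
#' position.  Frames are stored as one `frames x h x w` array per occupied
#' subfield, keyed `"<row>_<col>"`.
#'
#' @slot frames named list of 3D arrays (frames x h x w).
#' @slot gridShape chessboard grid (rows, cols).
#' @slot frameRate frames per second.
#' @slot centers n_subfields x 3 matrix of subfield centers (micrometers).
#' @slot fillValue marker written into uncovered pixels (0 or NaN).
#' @exportClass ChessboardMovie
setClass("ChessboardMovie", representation(
  frames = "list", gridShape = "integer", frameRate = "numeric",
  centers = "matrix", fillValue = "numeric"))

setValidity("ChessboardMovie", function(object) {
  msg <- character()
  if (length(object@frames)) {
    nf <- vapply(object@frames, function(a) dim(a)[1L], integer(1))
    if (length(unique(nf)) != 1L)
      msg <- c(msg, "all subfields must share the frame count")
    hw <- vapply(object@frames, function(a) dim(a)[2L] * dim(a)[3L], numeric(1))
    if (any(hw <= 0)) msg <- c(msg, "subfield height and width must be > 0")
  }
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' ROI pixel masks
#'
#' Automatic-segmentation-style masks: per ROI the soma pixel coordinates and
#' weights, the neuropil pixel coordinates and weights, the home subfield and
#' the soma 3D position.  Pixel coordinates are (row, col) within the home
#' subfield frame; neuropil pixels may spill outside it before cleaning.
#'
#' @slot rois list; each element has `somaPix` (n x 2), `somaW`, `npPix`
#'   (m x 2), `npW`, `homeSubfield` (key `"<row>_<col>"`), `somaXYZ`.
#' @slot subfieldSize subfield pixel size (h, w).
#' @slot gridShape chessboard grid (rows, cols).
#' @exportClass RoiSet
setClass("RoiSet", representation(
  rois = "list", subfieldSize = "integer", gridShape = "integer"))

setValidity("RoiSet", function(object) {
  msg <- character()
  for (i in seq_along(object@rois)) {
    r <- object@rois[[i]]
    if (!all(c("somaPix", "somaW", "npPix", "npW", "homeSubfield") %in% names(r))) {
      msg <- c(msg, sprintf("ROI %d is missing required fields", i)); next
    }
    if (any(r$somaW < 0) || sum(r$somaW) <= 0)
      msg <- c(msg, sprintf("ROI %d soma weights must be >= 0 and not all zero", i))
    if (length(r$homeSubfield) != 1L)
      msg <- c(msg, sprintf("ROI %d must have exactly one home subfield", i))
  }
  if (length(msg)) msg else TRUE
})

#' Fluorescence traces
#'
#' Raw soma and neuropil fluorescence, the neuropil-corrected trace, the
#' percentile baseline F0 and the normalized dF/F, per ROI.
#'
#' @slot raw neurons x frames raw soma fluorescence (a.u.).
#' @slot neuropil neurons x frames neuropil fluorescence (a.u.).
#' @slot corrected neurons x frames after neuropil subtraction.
#' @slot dff neurons x frames normalized transients.
#' @slot f0 per-ROI baseline (a.u.).
#' @slot frameRate Hz.
#' @slot valid per-ROI flag; FALSE when all soma pixels were invalidated.
#' @exportClass FluorescenceTraces
setClass("FluorescenceTraces", representation(
  raw = "matrix", neuropil = "matrix", corrected = "matrix", dff = "matrix",
  f0 = "numeric", frameRate = "numeric", valid = "logical"))

#' Zone-end aligned responses
#'
#' dF/F tensor `neurons x time x trials`, time axis in seconds with 0 at the
#' zone end, with per-trial zone labels and identically aligned running speed.
#'
#' @slot responses 3D array neurons x time x trials.
#' @slot time time axis (s), last sample at 0.
#' @slot labels per-trial zone class, `"AVER"` or `"CTRL"`.
#' @slot velocity time x trials running speed resampled to the imaging rate.
#' @slot preWindow alignment window length (s).
#' @slot rate imaging rate (Hz).
#' @slot trialInfo per-trial metadata (entry/exit times, zone, dropped count
#'   in attributes).
#' @exportClass AlignedResponses
setClass("AlignedResponses", representation(
  responses = "array", time = "numeric", labels = "character",
  velocity = "matrix", preWindow = "numeric", rate = "numeric",
  trialInfo = "data.frame"))

setValidity("AlignedResponses", function(object) {
  d <- dim(object@responses)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "responses must be a 3D array")
  else {
    if (length(object@time) != d[2L])
      msg <- c(msg, "time axis must match dim 2 of responses")
    if (length(object@labels) != d[3L])
      msg <- c(msg, "labels must match dim 3 of responses")
    if (!all(object@labels %in% c("AVER", "CTRL")))
      msg <- c(msg, "labels must be AVER or CTRL")
  }
  if (length(msg)) msg else TRUE
})

#' Non-negative CP factors
#'
#' Result of the non-negative canonical polyadic (tensor component) analysis:
#' neuron, temporal and trial factor matrices, all entrywise non-negative.
#' Neuron and time columns are unit L2-normalized; the component scale is
#' absorbed into the trial factors.
#'
#' @slot neuron neurons x rank matrix.
#' @slot time timepoints x rank matrix.
#' @slot trial trials x rank matrix.
#' @slot rank number of components.
#' @slot error relative reconstruction error of the best restart.
#' @slot objective per-iteration relative error trace of the best restart.
#' @slot converged logical.
#' @exportClass CPFactors
setClass("CPFactors", representation(
  neuron = "matrix", time = "matrix", trial = "matrix", rank = "integer",
  error = "numeric", objective = "numeric", converged = "logical"))

setValidity("CPFactors", function(object) {
  msg <- character()
  if (min(object@neuron, object@time, object@trial) < -1e-12)
    msg <- c(msg, "all factor entries must be non-negative")
  if (ncol(object@neuron) != object@rank || ncol(object@time) != object@rank ||
      ncol(object@trial) != object@rank)
    msg <- c(msg, "factor matrices must have 'rank' columns")
  if (length(msg)) msg else TRUE
})

#' Brown-Conrady radial distortion model
#'
#' Purely radial polynomial distortion of a head-mounted-display optical
#' path: a point at normalized undistorted radius r maps to
#' `r * (1 + K1 r^2 + K2 r^4 + K3 r^6)`.  The model is the identity when all
#' coefficients vanish; the sign pattern of the coefficients distinguishes
#' barrel, pincushion and mustache distortion.
#'
#' @slot k radial coefficients (K1, K2, K3), dimensionless.
#' @slot center distortion center in normalized image coordinates.
#' @slot normRadius distance mapping to r = 1 (default: half image diagonal).
#' @exportClass DistortionModel
setClass("DistortionModel", representation(
  k = "numeric", center = "numeric", normRadius = "numeric"))

setValidity("DistortionModel", function(object) {
  msg <- character()
  if (length(object@k) != 3L || any(!is.finite(object@k)))
    msg <- c(msg, "'k' must be three finite coefficients")
  if (length(object@center) != 2L)
    msg <- c(msg, "'center' must be length 2")
  if (!is.finite(object@normRadius) || object@normRadius <= 0)
    msg <- c(msg, "'normRadius' must be > 0")
  if (length(msg)) msg else TRUE
})
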