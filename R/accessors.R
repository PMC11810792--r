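## Constructors, accessors and show methods

#' Build a simulation configuration
#'
#' @param seed integer RNG seed.
#' @param nNeurons number of somata (default 97, the typical per-animal ROI
#'   count of the chessboard-scan recordings).
#' @param imagingRate per-cell frame rate in Hz (default 14.31; realistic
#'   range roughly 11.2--20.5).
#' @param behaviorDt treadmill sampling step in s (the locomotion encoder
#'   reports position every 3 ms).
#' @param nTrialsPerZone grating-zone visits per zone type.
#' @param zones zone labels; the first is the aversive (0 degree) zone.
#' @param zoneGrace seconds allowed to escape before the first airpuff.
#' @param puffDuration airpuff pulse length (s).
#' @param puffPeriod airpuff pulse period (s).
#' @param immobilityTimeout immobility before a forced teleport (s).
#' @param meanInterteleport mean neutral interval between zone visits (s).
#' @param noiseSd additive trace noise (dF/F units).
#' @param neuropilMix neuropil contamination fraction (default 0.6, matched
#'   by the 60 percent subtraction in the pipeline).
#' @param gridShape chessboard grid (rows, cols).
#' @param subfieldSize subfield pixel size (h, w).
#' @param hubFraction fraction of hub cells.
#' @param rampDuration ramp rise time before zone end (s).
#' @param baselineVelocity mean running speed (cm/s).
#' @param velocitySd SD of the slow running-speed fluctuation (cm/s).
#' @param pImmobile probability a neutral period freezes into immobility.
#' @param fillValue invalid-pixel marker, 0 or NaN.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nNeurons = 20, gridShape = c(5, 4))
#' @export
simConfig <- function(seed = 1L, nNeurons = 97L, imagingRate = 14.31,
                      behaviorDt = 0.003, nTrialsPerZone = 10L,
                      zones = c("AVER_0", "CTRL_45"), zoneGrace = 3.5,
                      puffDuration = 0.4, puffPeriod = 0.8,
                      immobilityTimeout = 8, meanInterteleport = 20,
                      noiseSd = 0.05, neuropilMix = 0.6,
                      gridShape = c(10L, 10L), subfieldSize = c(24L, 24L),
                      hubFraction = 0.1, rampDuration = 3,
                      baselineVelocity = 8, velocitySd = 2,
                      pImmobile = 0, fillValue = 0) {
  num <- c(imagingRate = imagingRate, behaviorDt = behaviorDt,
           zoneGrace = zoneGrace, puffDuration = puffDuration,
           puffPeriod = puffPeriod, immobilityTimeout = immobilityTimeout,
           meanInterteleport = meanInterteleport, noiseSd = noiseSd,
           neuropilMix = neuropilMix, hubFraction = hubFraction,
           rampDuration = rampDuration, baselineVelocity = baselineVelocity,
           velocitySd = velocitySd, pImmobile = pImmobile)
  bad <- names(num)[!is.finite(num)]
  if (length(bad))
    stop("non-finite configuration value for field(s): ",
         paste(bad, collapse = ", "))
  new("SimConfig", seed = as.integer(seed), nNeurons = as.integer(nNeurons),
      imagingRate = imagingRate, behaviorDt = behaviorDt,
      nTrialsPerZone = as.integer(nTrialsPerZone), zones = zones,
      zoneGrace = zoneGrace, puffDuration = puffDuration,
      puffPeriod = puffPeriod, immobilityTimeout = immobilityTimeout,
      meanInterteleport = meanInterteleport, noiseSd = noiseSd,
      neuropilMix = neuropilMix, gridShape = as.integer(gridShape),
      subfieldSize = as.integer(subfieldSize), hubFraction = hubFraction,
      rampDuration = rampDuration, baselineVelocity = baselineVelocity,
      velocitySd = velocitySd, pImmobile = pImmobile, fillValue = fillValue)
}

#' Session event table accessor
#' @param object a [SessionLog-class].
#' @return data.frame with columns `time`, `kind`, `zone`.
#' @export
setGeneric("sessionEvents", function(object) standardGeneric("sessionEvents"))
#' @export
setMethod("sessionEvents", "SessionLog", function(object) object@events)

#' Velocity trace accessor
#' @param object a [SessionLog-class].
#' @export
setGeneric("velocityTrace", function(object) standardGeneric("velocityTrace"))
#' @export
setMethod("velocityTrace", "SessionLog", function(object) object@velocity)

#' Per-trial summary accessor
#' @param object a [SessionLog-class].
#' @export
setGeneric("sessionTrials", function(object) standardGeneric("sessionTrials"))
#' @export
setMethod("sessionTrials", "SessionLog", function(object) object@trials)

#' Aligned response tensor accessor
#' @param object an [AlignedResponses-class].
#' @export
setGeneric("responseTensor", function(object) standardGeneric("responseTensor"))
#' @export
setMethod("responseTensor", "AlignedResponses", function(object) object@responses)

#' Time axis accessor
#' @param object an [AlignedResponses-class].
#' @export
setGeneric("timeAxis", function(object) standardGeneric("timeAxis"))
#' @export
setMethod("timeAxis", "AlignedResponses", function(object) object@time)

#' Trial zone labels accessor
#' @param object an [AlignedResponses-class].
#' @export
setGeneric("zoneLabels", function(object) standardGeneric("zoneLabels"))
#' @export
setMethod("zoneLabels", "AlignedResponses", function(object) object@labels)

#' Aligned velocity accessor
#' @param object an [AlignedResponses-class].
#' @export
setGeneric("alignedVelocity", function(object) standardGeneric("alignedVelocity"))
#' @export
setMethod("alignedVelocity", "AlignedResponses", function(object) object@velocity)

#' CP factor matrix accessor
#' @param object a [CPFactors-class].
#' @param mode one of `"neuron"`, `"time"`, `"trial"`.
#' @export
setGeneric("factorMatrix", function(object, mode) standardGeneric("factorMatrix"))
#' @export
setMethod("factorMatrix", "CPFactors", function(object, mode) {
  slot(object, match.arg(mode, c("neuron", "time", "trial")))
})

#' dF/F matrix accessor
#' @param object a [FluorescenceTraces-class].
#' @export
setGeneric("dff", function(object) standardGeneric("dff"))
#' @export
setMethod("dff", "FluorescenceTraces", function(object) object@dff)

#' Distortion coefficient accessor
#' @param object a [DistortionModel-class].
#' @export
setGeneric("distortionCoefs", function(object) standardGeneric("distortionCoefs"))
#' @export
setMethod("distortionCoefs", "DistortionModel", function(object) object@k)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nNeurons, "neurons,",
      length(object@zones), "zones,", object@nTrialsPerZone,
      "trials/zone\n  imaging", object@imagingRate, "Hz | behavior dt",
      object@behaviorDt, "s | grid",
      paste(object@gridShape, collapse = "x"), "\n")
})

setMethod("show", "SessionLog", function(object) {
  cat("SessionLog:", nrow(object@events), "events,",
      nrow(object@trials), "zone visits,",
      sprintf("%.1f s", object@duration), "\n")
})

setMethod("show", "ChessboardMovie", function(object) {
  nf <- if (length(object@frames)) dim(object@frames[[1L]])[1L] else 0L
  cat("ChessboardMovie:", length(object@frames), "subfields x", nf,
      "frames @", object@frameRate, "Hz (grid",
      paste(object@gridShape, collapse = "x"), ")\n")
})

setMethod("show", "RoiSet", function(object) {
  cat("RoiSet:", length(object@rois), "ROIs, subfield",
      paste(object@subfieldSize, collapse = "x"), "px\n")
})

setMethod("show", "FluorescenceTraces", function(object) {
  cat("FluorescenceTraces:", nrow(object@dff), "ROIs x", ncol(object@dff),
      "frames @", object@frameRate, "Hz;", sum(!object@valid),
      "invalid ROI(s)\n")
})

setMethod("show", "AlignedResponses", function(object) {
  d <- dim(object@responses)
  cat("AlignedResponses:", d[1L], "neurons x", d[2L], "timepoints x",
      d[3L], "trials (", sum(object@labels == "AVER"), "AVER /",
      sum(object@labels == "CTRL"), "CTRL )\n")
})

setMethod("show", "CPFactors", function(object) {
  cat("CPFactors: rank", object@rank, "| relative error",
      sprintf("%.4g", object@error),
      if (object@converged) "(converged)" else "(not converged)", "\n")
})

setMethod("show", "DistortionModel", function(object) {
  cat("DistortionModel: K = (",
      paste(sprintf("%.4g", object@k), collapse = ", "),
      ") ->", classifyDistortion(object), "\n")
})
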