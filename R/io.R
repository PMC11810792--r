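## Plain-text / TIFF interchange: session CSVs, ROI masks and ground truth
## as JSON, chessboard movies as multi-page TIFF per subfield.

#' Write / read a session log as CSV
#'
#' Events go to `<prefix>_events.csv` (time, kind, zone), the velocity
#' trace to `<prefix>_velocity.csv` (time, velocity, position) and the
#' trial table to `<prefix>_trials.csv`.
#'
#' @param session a [SessionLog-class].
#' @param prefix file path prefix.
#' @return `writeSessionCsv`: the prefix, invisibly.  `readSessionCsv`: a
#'   [SessionLog-class].
#' @export
writeSessionCsv <- function(session, prefix) {
  write.csv(session@events, paste0(prefix, "_events.csv"), row.names = FALSE)
  write.csv(session@velocity, paste0(prefix, "_velocity.csv"),
            row.names = FALSE)
  write.csv(session@trials, paste0(prefix, "_trials.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname writeSessionCsv
#' @param behaviorDt sampling step of the stored velocity trace (s);
#'   inferred from the trace when NULL.
#' @param zoneGrace grace period metadata (s).
#' @export
readSessionCsv <- function(prefix, behaviorDt = NULL, zoneGrace = 3.5) {
  ev <- read.csv(paste0(prefix, "_events.csv"))
  vel <- read.csv(paste0(prefix, "_velocity.csv"))
  tr <- read.csv(paste0(prefix, "_trials.csv"))
  if (is.null(behaviorDt)) behaviorDt <- median(diff(vel$time))
  new("SessionLog", events = ev, velocity = vel, behaviorDt = behaviorDt,
      duration = max(vel$time), trials = tr, zoneGrace = zoneGrace)
}

#' Write / read ROI masks as JSON
#'
#' Per ROI: soma pixel (row, col) coordinates and weights, neuropil pixel
#' coordinates and weights, home subfield key and soma 3D position.
#'
#' @param roiset a [RoiSet-class].
#' @param path JSON file path.
#' @export
writeRoiSetJson <- function(roiset, path) {
  payload <- list(
    subfieldSize = roiset@subfieldSize, gridShape = roiset@gridShape,
    rois = lapply(roiset@rois, function(r)
      list(somaPix = unname(as.matrix(r$somaPix)), somaW = r$somaW,
           npPix = unname(as.matrix(r$npPix)), npW = r$npW,
           homeSubfield = r$homeSubfield,
           somaXYZ = if (is.null(r$somaXYZ)) NULL else r$somaXYZ)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRoiSetJson
#' @export
readRoiSetJson <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  rois <- lapply(seq_len(if (is.data.frame(p$rois)) nrow(p$rois)
                         else length(p$rois)), function(i) {
    r <- if (is.data.frame(p$rois)) lapply(p$rois, `[[`, i) else p$rois[[i]]
    r$somaPix <- matrix(unlist(r$somaPix), ncol = 2L)
    r$npPix <- matrix(unlist(r$npPix), ncol = 2L)
    r$somaW <- as.numeric(unlist(r$somaW))
    r$npW <- as.numeric(unlist(r$npW))
    r
  })
  new("RoiSet", rois = rois, subfieldSize = as.integer(p$subfieldSize),
      gridShape = as.integer(p$gridShape))
}

#' Write ground truth as JSON
#'
#' @param truth output of [generateGroundTruth()].
#' @param path JSON file path.
#' @export
writeGroundTruthJson <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write / read a chessboard movie as multi-page TIFF
#'
#' One 32-bit float multi-page TIFF per subfield, named
#' `subfield_<row>_<col>.tif`, plus a `movie_meta.json` with grid shape,
#' frame rate, centers and fill value.  Intensities are stored divided by
#' `scale` (TIFF float convention keeps them exactly).
#'
#' @param movie a [ChessboardMovie-class].
#' @param dir output directory (created if missing).
#' @param scale intensity scale divisor applied before writing.
#' @export
writeMovieTiff <- function(movie, dir, scale = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(movie@frames)) {
    a <- movie@frames[[key]]
    pages <- lapply(seq_len(dim(a)[1L]), function(f) a[f, , ] / scale)
    tiff::writeTIFF(pages, file.path(dir, paste0("subfield_", key, ".tif")),
                    bits.per.sample = 32L)
  }
  jsonlite::write_json(
    list(gridShape = movie@gridShape, frameRate = movie@frameRate,
         fillValue = movie@fillValue, scale = scale,
         centers = movie@centers, keys = names(movie@frames)),
    file.path(dir, "movie_meta.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeMovieTiff
#' @export
readMovieTiff <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "movie_meta.json"),
                              simplifyVector = TRUE)
  frames <- list()
  for (key in meta$keys) {
    pages <- tiff::readTIFF(file.path(dir, paste0("subfield_", key, ".tif")),
                            all = TRUE)
    a <- array(0, dim = c(length(pages), nrow(pages[[1L]]),
                          ncol(pages[[1L]])))
    for (f in seq_along(pages)) a[f, , ] <- pages[[f]] * meta$scale
    frames[[key]] <- a
  }
  new("ChessboardMovie", frames = frames,
      gridShape = as.integer(meta$gridShape), frameRate = meta$frameRate,
      centers = matrix(unlist(meta$centers), ncol = 3L),
      fillValue = meta$fillValue)
}
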