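## Rendering chessboard-scan movies from ground truth traces.

## integer shift with fill: content moves +dy rows, +dx cols
.shiftMatrix <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  srcR <- seq_len(h) - dy
  srcC <- seq_len(w) - dx
  okR <- srcR >= 1L & srcR <= h
  okC <- srcC >= 1L & srcC <= w
  out[okR, okC] <- m[srcR[okR], srcC[okC]]
  out
}

.subfieldKey <- function(r, c) paste0(r, "_", c)

#' Render a synthetic chessboard-scan movie
#'
#' Renders one soma per occupied subfield of an m x n chessboard scan: a
#' soma disk whose pixel intensity follows the neuron's fluorescence
#' `F0 * (1 + dff)`, contaminated by `neuropilMix` times a shared background
#' (neuropil) trace; an annular neuropil region carrying the background
#' trace; optional per-frame rigid motion (applied to all subfields, filled
#' with `fillValue` where pixels leave the frame) and shot-like Gaussian
#' noise.  The returned `RoiSet` records the true soma/neuropil pixels,
#' weights, home subfield and 3D soma position, so that trace extraction can
#' be validated exactly.
#'
#' @param truth output of [generateGroundTruth()].
#' @param traces output of [generateTransients()] (its `dff` matrix drives
#'   soma intensities).
#' @param config a [SimConfig-class].
#' @param motion nFrames x 2 integer matrix of (row, col) shifts per frame,
#'   or NULL for no motion.  Shifts must stay below a quarter of the
#'   subfield size, otherwise registration would be ill-posed.
#' @param somaF0 baseline soma fluorescence (a.u.).
#' @param npAmplitude amplitude of the shared neuropil background trace
#'   (a.u.); 0 renders contamination-free somata.
#' @param pixelNoiseSd per-pixel Gaussian noise SD (a.u.).
#' @param somaRadius,npInner,npOuter soma disk and neuropil annulus radii
#'   (px).
#' @param seed RNG seed; defaults to `config@seed`.
#' @return list with `movie` ([ChessboardMovie-class]), `rois`
#'   ([RoiSet-class]), `npTrace` (the shared background trace) and
#'   `somaF0`.
#' @export
generateChessboardMovie <- function(truth, traces, config, motion = NULL,
                                    somaF0 = 50, npAmplitude = 20,
                                    pixelNoiseSd = 0, somaRadius = 4,
                                    npInner = 5.5, npOuter = 8.5,
                                    seed = config@seed) {
  set.seed(seed + 2L)
  nn <- nrow(truth$neurons)
  nf <- ncol(traces$dff)
  h <- config@subfieldSize[1L]; w <- config@subfieldSize[2L]
  if (is.null(motion)) motion <- matrix(0L, nf, 2L)
  if (nrow(motion) != nf) stop("motion must have one (row, col) shift per frame")
  if (any(abs(motion) > min(h, w) / 4))
    stop("motion shifts exceed a quarter of the subfield size; registration would be ill-posed")

  ## shared neuropil background: smooth positive trace
  npTrace <- npAmplitude * (1 + 0.4 * .slowFluct(nf, 1 / config@imagingRate, 1))
  npTrace <- pmax(npTrace, 0)

  rows <- config@gridShape[1L]; cols <- config@gridShape[2L]
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  px <- expand.grid(r = seq_len(h), c = seq_len(w))
  d2 <- (px$r - cr)^2 + (px$c - cc)^2
  somaSel <- d2 <= somaRadius^2
  ## annulus measured from the soma center; may spill outside the subfield
  annAll <- expand.grid(r = seq_len(h) - round(h / 2), c = seq_len(w) - round(w / 2))
  annAll$r <- annAll$r + round(cr); annAll$c <- annAll$c + round(cc)
  dAnn <- sqrt((annAll$r - cr)^2 + (annAll$c - cc)^2)
  annSel <- dAnn > npInner & dAnn <= npOuter
  somaPix <- as.matrix(px[somaSel, c("r", "c")])
  npPix <- as.matrix(annAll[annSel, c("r", "c")])
  somaW <- exp(-d2[somaSel] / (2 * somaRadius^2))
  somaW <- somaW / sum(somaW)

  frames <- list(); centers <- NULL; rois <- vector("list", nn)
  for (i in seq_len(nn)) {
    r <- ((i - 1L) %/% cols) + 1L
    c <- ((i - 1L) %% cols) + 1L
    key <- .subfieldKey(r, c)
    somaTrace <- somaF0 * (1 + traces$dff[i, ]) +
      config@neuropilMix * npTrace
    base <- matrix(5, h, w)
    inb <- npPix[, 1L] >= 1 & npPix[, 1L] <= h & npPix[, 2L] >= 1 & npPix[, 2L] <= w
    arr <- array(0, dim = c(nf, h, w))
    for (f in seq_len(nf)) {
      img <- base
      img[npPix[inb, , drop = FALSE]] <- npTrace[f]
      img[somaPix] <- somaTrace[f]
      if (pixelNoiseSd > 0)
        img <- img + matrix(rnorm(h * w, 0, pixelNoiseSd), h, w)
      if (motion[f, 1L] != 0 || motion[f, 2L] != 0)
        img <- .shiftMatrix(img, motion[f, 1L], motion[f, 2L],
                            fill = config@fillValue)
      arr[f, , ] <- img
    }
    frames[[key]] <- arr
    centers <- rbind(centers, as.numeric(truth$neurons[i, c("x", "y", "z")]))
    rois[[i]] <- list(somaPix = somaPix, somaW = somaW,
                      npPix = npPix, npW = rep(1 / nrow(npPix), nrow(npPix)),
                      homeSubfield = key,
                      somaXYZ = as.numeric(truth$neurons[i, c("x", "y", "z")]))
  }
  movie <- new("ChessboardMovie", frames = frames,
               gridShape = config@gridShape, frameRate = config@imagingRate,
               centers = centers, fillValue = config@fillValue)
  roiset <- new("RoiSet", rois = rois, subfieldSize = config@subfieldSize,
                gridShape = config@gridShape)
  list(movie = movie, rois = roiset, npTrace = npTrace, somaF0 = somaF0)
}
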