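## Pixel-level mask cleaning, neuropil decontamination and dF/F.

## zero and NaN both mark uncovered pixels; a custom finite fill value is
## honored too
.invalidPixel <- function(x, fillValue) {
  bad <- is.na(x) | x == 0
  if (is.finite(fillValue) && fillValue != 0) bad <- bad | x == fillValue
  bad
}

#' Clean ROI (soma) pixels against fill-value contamination
#'
#' After registration, pixels displaced outside the imaging field carry the
#' fill value (zero or NaN).  Each soma pixel's fluorescence trace is
#' extracted from the ROI's home subfield; any pixel whose trace contains at
#' least one invalid value is excluded, and the remaining segmentation
#' weights are renormalized to sum to one.  An ROI that loses all its pixels
#' is flagged invalid (and excluded downstream) rather than raising an
#' error.  The operation is idempotent.
#'
#' @param movie a registered [ChessboardMovie-class].
#' @param roiset a [RoiSet-class].
#' @return list per ROI with `pixTraces` (kept pixels x frames), `weights`
#'   (renormalized), `keptPix` (coordinates), `dropped` (count), `valid`.
#' @export
cleanRoiPixels <- function(movie, roiset) {
  lapply(roiset@rois, function(roi) {
    a <- movie@frames[[roi$homeSubfield]]
    if (is.null(a)) stop("ROI home subfield not present in movie: ",
                         roi$homeSubfield)
    h <- dim(a)[2L]; w <- dim(a)[3L]
    pix <- roi$somaPix
    inb <- pix[, 1L] >= 1 & pix[, 1L] <= h & pix[, 2L] >= 1 & pix[, 2L] <= w
    traces <- matrix(NA_real_, nrow(pix), dim(a)[1L])
    for (p in which(inb)) traces[p, ] <- a[, pix[p, 1L], pix[p, 2L]]
    bad <- !inb | apply(traces, 1L, function(x)
      any(.invalidPixel(x, movie@fillValue)))
    kept <- !bad
    if (!any(kept)) {
      return(list(pixTraces = traces[0L, , drop = FALSE],
                  weights = numeric(0), keptPix = pix[0L, , drop = FALSE],
                  dropped = sum(bad), valid = FALSE))
    }
    wts <- roi$somaW[kept]
    list(pixTraces = traces[kept, , drop = FALSE], weights = wts / sum(wts),
         keptPix = pix[kept, , drop = FALSE], dropped = sum(bad),
         valid = TRUE)
  })
}

#' Clean neuropil pixels against chessboard-frame and ROI overlap
#'
#' The automatic segmentation does not know the chessboard borders: neuropil
#' annuli frequently spill into neighboring subfields, which sit elsewhere
#' in the scanned 3D volume.  Neuropil pixels outside the home subfield's
#' pixel rectangle, or overlapping any ROI's soma pixels in the same
#' subfield (including the ROI's own soma), are removed; the remaining
#' pixels are averaged with equal weight.  An ROI whose neuropil empties
#' completely is flagged (`npEmpty`); its neuropil trace is then defined as
#' zero, so the subsequent correction reduces to the identity.
#'
#' @param roiset a [RoiSet-class].
#' @return a [RoiSet-class] with cleaned neuropil pixels and equal weights;
#'   per-ROI attributes `npDropped` and `npEmpty` are stored in each ROI
#'   element.
#' @export
cleanNeuropilPixels <- function(roiset) {
  h <- roiset@subfieldSize[1L]; w <- roiset@subfieldSize[2L]
  somaBySubfield <- list()
  for (roi in roiset@rois) {
    key <- roi$homeSubfield
    somaBySubfield[[key]] <- rbind(somaBySubfield[[key]], roi$somaPix)
  }
  rois <- lapply(roiset@rois, function(roi) {
    np <- roi$npPix
    inb <- np[, 1L] >= 1 & np[, 1L] <= h & np[, 2L] >= 1 & np[, 2L] <= w
    soma <- somaBySubfield[[roi$homeSubfield]]
    somaKey <- paste(soma[, 1L], soma[, 2L])
    overlap <- paste(np[, 1L], np[, 2L]) %in% somaKey
    keep <- inb & !overlap
    roi$npDropped <- sum(!keep)
    roi$npEmpty <- !any(keep)
    roi$npPix <- np[keep, , drop = FALSE]
    roi$npW <- rep(if (any(keep)) 1 / sum(keep) else numeric(0), sum(keep))
    roi
  })
  out <- roiset
  out@rois <- rois
  out
}

#' Subtract scaled neuropil from a raw fluorescence trace
#'
#' `corrected(t) = F_roi(t) - mix * F_np(t)`, with 60 percent subtraction by
#' default.
#'
#' @param fRoi raw soma fluorescence (a.u.).
#' @param fNp neuropil fluorescence (a.u.), same length.
#' @param mix contamination fraction in `[0, 1]`.
#' @return corrected trace.
#' @examples
#' neuropilCorrect(rep(10, 5), rep(5, 5), 0.6)  # 7 7 7 7 7
#' @export
neuropilCorrect <- function(fRoi, fNp, mix = 0.6) {
  if (length(fRoi) != length(fNp))
    stop(sprintf("length mismatch: soma trace has %d samples, neuropil %d",
                 length(fRoi), length(fNp)))
  if (mix < 0 || mix > 1) stop("'mix' must lie in [0, 1]")
  fRoi - mix * fNp
}

#' Percentile-baseline dF/F
#'
#' The baseline F0 is the 8th percentile of all samples of the cell's
#' (neuropil-corrected) day trace; the normalized transient is
#' `(F - F0) / F0`.  The percentile uses linear interpolation between order
#' statistics by default (`convention = "linear"`, the dominant array-library
#' convention); a nearest-rank variant is available.
#'
#' @param f fluorescence trace (a.u.), at least 2 samples.
#' @param percentile baseline percentile (default 8).
#' @param convention `"linear"` or `"nearest"` rank.
#' @param roiId optional label used in error messages.
#' @return list with `dff` and `f0`.
#' @examples
#' computeDFF(1:100)$f0  # 8.92
#' @export
computeDFF <- function(f, percentile = 8, convention = c("linear", "nearest"),
                       roiId = NULL) {
  convention <- match.arg(convention)
  if (length(f) < 2L) stop("need at least 2 samples")
  type <- if (convention == "linear") 7L else 1L
  f0 <- unname(quantile(f, percentile / 100, type = type, names = FALSE))
  if (!is.finite(f0) || f0 <= 0)
    stop(sprintf(
      "baseline F0 = %.4g is not positive%s: corrected trace went nonpositive at baseline",
      f0, if (is.null(roiId)) "" else paste0(" for ROI ", roiId)))
  list(dff = (f - f0) / f0, f0 = f0)
}

#' Full fluorescence extraction pipeline
#'
#' Chains the chessboard pipeline: optional per-subfield rigid registration,
#' neuropil mask cleaning (chessboard frame + ROI overlap), soma pixel
#' cleaning (fill-value contamination), weighted soma and equal-weight
#' neuropil trace formation, 60 percent neuropil subtraction and
#' percentile-baseline dF/F.
#'
#' @param movie a [ChessboardMovie-class].
#' @param roiset a [RoiSet-class].
#' @param mix neuropil subtraction fraction (default 0.6).
#' @param percentile baseline percentile (default 8).
#' @param register run rigid motion correction first.
#' @param upsample subpixel refinement factor for registration.
#' @return a [FluorescenceTraces-class]; invalid ROIs carry NA traces and
#'   `valid = FALSE`.
#' @export
extractTraces <- function(movie, roiset, mix = 0.6, percentile = 8,
                          register = FALSE, upsample = 10) {
  if (register) movie <- registerSubfields(movie, upsample = upsample)$corrected
  roiset <- cleanNeuropilPixels(roiset)
  cleaned <- cleanRoiPixels(movie, roiset)
  nf <- dim(movie@frames[[1L]])[1L]
  n <- length(cleaned)
  raw <- np <- corr <- dffM <- matrix(NA_real_, n, nf)
  f0 <- rep(NA_real_, n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    cl <- cleaned[[i]]
    if (!cl$valid) next
    raw[i, ] <- colSums(cl$pixTraces * cl$weights)
    roi <- roiset@rois[[i]]
    if (isTRUE(roi$npEmpty) || nrow(roi$npPix) == 0L) {
      np[i, ] <- 0
    } else {
      a <- movie@frames[[roi$homeSubfield]]
      npT <- matrix(NA_real_, nrow(roi$npPix), nf)
      for (p in seq_len(nrow(roi$npPix)))
        npT[p, ] <- a[, roi$npPix[p, 1L], roi$npPix[p, 2L]]
      np[i, ] <- colMeans(npT)
    }
    corr[i, ] <- neuropilCorrect(raw[i, ], np[i, ], mix)
    d <- computeDFF(corr[i, ], percentile = percentile, roiId = i)
    dffM[i, ] <- d$dff
    f0[i] <- d$f0
    valid[i] <- TRUE
  }
  new("FluorescenceTraces", raw = raw, neuropil = np, corrected = corr,
      dff = dffM, f0 = f0, frameRate = movie@frameRate, valid = valid)
}
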