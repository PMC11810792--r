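## Per-subfield rigid motion correction by cross-correlation with
## upsampled-DFT subpixel refinement.

## cross-correlation peak between image `img` and reference `ref`
## (both matrices); returns the (dy, dx) such that img ~ ref shifted by
## (dy, dx).  Integer peak from the FFT cross-correlation, then local
## refinement on a 1/upsample grid via a matrix-multiplication DFT.
.estimateShift <- function(img, ref, upsample = 10) {
  h <- nrow(img); w <- ncol(img)
  if (sd(img) == 0 || sd(ref) == 0)
    return(list(shift = c(0, 0), flat = TRUE))
  F1 <- fft(img - mean(img))
  F2 <- fft(ref - mean(ref))
  P <- F1 * Conj(F2)
  cc <- Re(fft(P, inverse = TRUE))
  pk <- unname(which(cc == max(cc), arr.ind = TRUE)[1L, ])
  dy <- pk[1L] - 1L; dx <- pk[2L] - 1L
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  if (upsample <= 1) return(list(shift = c(dy, dx), flat = FALSE))
  ## fine grid around the integer peak
  fy <- c(0:floor((h - 1) / 2), -(ceiling((h - 1) / 2):1)) / h
  fx <- c(0:floor((w - 1) / 2), -(ceiling((w - 1) / 2):1)) / w
  uy <- dy + seq(-1, 1, by = 1 / upsample)
  ux <- dx + seq(-1, 1, by = 1 / upsample)
  Wy <- exp(2i * pi * outer(uy, fy))           # |uy| x h
  Wx <- exp(2i * pi * outer(fx, ux))           # w x |ux|
  ccFine <- Re(Wy %*% P %*% Wx)
  pk2 <- which(ccFine == max(ccFine), arr.ind = TRUE)[1L, ]
  list(shift = c(uy[pk2[1L]], ux[pk2[2L]]), flat = FALSE)
}

#' Rigid motion correction of a chessboard movie
#'
#' Every subfield (chessboard piece) is rigidly motion corrected separately:
#' per-frame (row, col) shifts are estimated by cross-correlation against
#' the per-subfield reference image -- by default the maximum-intensity
#' projection over the first measurement unit -- with subpixel refinement on
#' a `1/upsample`-pixel grid.  The correction applied to the frames is the
#' rounded shift; pixels uncovered by the shift are set to the movie's fill
#' value.  A zero-variance (flat) subfield yields shift (0, 0) with a
#' warning flag rather than an error.
#'
#' @param movie a [ChessboardMovie-class].
#' @param reference optional named list of reference images per subfield;
#'   defaults to the max projection of the first `refFrames` frames.
#' @param upsample subpixel refinement factor (10 = 0.1-px precision; 1
#'   disables refinement).
#' @param refFrames number of leading frames forming the first measurement
#'   unit (default: all frames).
#' @return list with `shifts` (named list of nFrames x 2 matrices),
#'   `corrected` (a [ChessboardMovie-class]), `flatFlags` (named logical),
#'   `global` (nFrames x 2 mean displacement across subfields).
#' @export
registerSubfields <- function(movie, reference = NULL, upsample = 10,
                              refFrames = NULL) {
  keys <- names(movie@frames)
  nf <- dim(movie@frames[[1L]])[1L]
  if (is.null(refFrames)) refFrames <- nf
  refFrames <- min(refFrames, nf)
  if (is.null(reference)) {
    reference <- lapply(movie@frames, function(a) {
      apply(a[seq_len(refFrames), , , drop = FALSE], c(2L, 3L), max)
    })
  }
  shifts <- list(); flat <- logical(length(keys)); names(flat) <- keys
  corrected <- movie@frames
  for (k in keys) {
    a <- movie@frames[[k]]
    sh <- matrix(0, nf, 2L, dimnames = list(NULL, c("dy", "dx")))
    isFlat <- FALSE
    for (f in seq_len(nf)) {
      est <- .estimateShift(a[f, , ], reference[[k]], upsample = upsample)
      sh[f, ] <- est$shift
      isFlat <- isFlat || est$flat
      rs <- round(est$shift)
      if (rs[1L] != 0 || rs[2L] != 0)
        corrected[[k]][f, , ] <- .shiftMatrix(a[f, , ], -rs[1L], -rs[2L],
                                              fill = movie@fillValue)
    }
    shifts[[k]] <- sh
    flat[k] <- isFlat
  }
  global <- Reduce(`+`, shifts) / length(shifts)
  out <- movie
  out@frames <- corrected
  list(shifts = shifts, corrected = out, flatFlags = flat, global = global)
}
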