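## Brown-Conrady radial distortion model of the head-mounted display
## optics: forward model, numerical inverse, coefficient estimation and
## distortion-type classification.

#' Construct a radial distortion model
#'
#' @param k radial coefficients (K1, K2, K3); the identity when all zero.
#' @param center distortion center in normalized image coordinates.
#' @param normRadius distance mapping to r = 1; conventionally half the
#'   image diagonal (the coefficients rescale with this choice).
#' @return a [DistortionModel-class].
#' @examples
#' distortionModel(c(0.1, 0.02, 0))
#' @export
distortionModel <- function(k = c(0, 0, 0), center = c(0, 0),
                            normRadius = 1) {
  new("DistortionModel", k = as.numeric(k), center = as.numeric(center),
      normRadius = normRadius)
}

.radialFactor <- function(r2, k) 1 + k[1L] * r2 + k[2L] * r2^2 + k[3L] * r2^3

## d(r * factor)/dr > 0 required for invertibility
.isMonotone <- function(model, rMax) {
  r <- seq(0, rMax, length.out = 257L)
  r2 <- r^2
  k <- model@k
  all(1 + 3 * k[1L] * r2 + 5 * k[2L] * r2^2 + 7 * k[3L] * r2^3 > 0)
}

.toRadial <- function(points, model) {
  points <- matrix(points, ncol = 2L)
  dx <- (points[, 1L] - model@center[1L]) / model@normRadius
  dy <- (points[, 2L] - model@center[2L]) / model@normRadius
  list(dx = dx, dy = dy, r2 = dx^2 + dy^2)
}

#' Apply radial distortion to undistorted points
#'
#' `x_d = x_u (1 + K1 r^2 + K2 r^4 + K3 r^6)` (and identically for y),
#' with `r` the normalized distance of the undistorted point from the
#' center.  The center is a fixed point for any coefficients.
#'
#' @param points n x 2 matrix (or length-2 vector) of undistorted
#'   normalized coordinates.
#' @param model a [DistortionModel-class].
#' @return n x 2 matrix of distorted coordinates.
#' @examples
#' applyDistortion(c(0.5, 0), distortionModel(c(0.1, 0, 0)))  # 0.5125 0
#' @export
applyDistortion <- function(points, model) {
  rad <- .toRadial(points, model)
  rMax <- sqrt(max(rad$r2))
  if (!.isMonotone(model, rMax))
    stop("radial polynomial is not monotone on the requested domain; the inverse would be ill-defined")
  f <- .radialFactor(rad$r2, model@k)
  cbind(model@center[1L] + rad$dx * f * model@normRadius,
        model@center[2L] + rad$dy * f * model@normRadius)
}

#' Invert radial distortion numerically
#'
#' Fixed-point iteration `x_u <- x_d / f(r(x_u))` on the radius, with a
#' Newton fallback, until the forward-mapped residual is below `tol`.
#'
#' @param points n x 2 distorted coordinates.
#' @param model a [DistortionModel-class] (monotone on the domain).
#' @param tol residual tolerance (normalized units).
#' @param maxIter iteration cap.
#' @return n x 2 matrix of undistorted coordinates.
#' @export
invertDistortion <- function(points, model, tol = 1e-9, maxIter = 100) {
  rad <- .toRadial(points, model)
  rd <- sqrt(rad$r2)
  k <- model@k
  ru <- rd
  for (it in seq_len(maxIter)) {
    f <- .radialFactor(ru^2, k)
    ruNew <- rd / f
    if (max(abs(ruNew - ru)) < tol / 10) { ru <- ruNew; break }
    ru <- ruNew
  }
  ## Newton fallback on g(ru) = ru * f(ru^2) - rd for stragglers
  g <- function(r) r * .radialFactor(r^2, k) - rd
  gp <- function(r) 1 + 3 * k[1L] * r^2 + 5 * k[2L] * r^4 + 7 * k[3L] * r^6
  bad <- abs(g(ru)) > tol
  it <- 0L
  while (any(bad) && it < maxIter) {
    ru[bad] <- ru[bad] - g(ru)[bad] / gp(ru[bad])
    bad <- abs(g(ru)) > tol
    it <- it + 1L
  }
  scaleF <- ifelse(rd > 0, ru / rd, 1)
  und <- cbind(model@center[1L] + rad$dx * scaleF * model@normRadius,
               model@center[2L] + rad$dy * scaleF * model@normRadius)
  resid <- max(abs(applyDistortion(und, model) - matrix(points, ncol = 2L)))
  if (resid > tol * 10)
    stop(sprintf("inverse distortion did not converge; worst residual %.3g", resid))
  und
}

#' Estimate distortion coefficients from point correspondences
#'
#' Least-squares fit of (K1, K2, K3) minimizing the reprojection error of
#' undistorted-to-distorted point pairs from a calibration grid, via damped
#' Levenberg-Marquardt iterations.
#'
#' @param undistorted,distorted n x 2 matrices of corresponding points
#'   (>= 6 non-degenerate pairs spanning several radii).
#' @param center,normRadius normalization convention of the fitted model.
#' @return list with `model` (a [DistortionModel-class]), `rms` residual,
#'   `residuals`.
#' @export
estimateDistortion <- function(undistorted, distorted, center = c(0, 0),
                               normRadius = 1) {
  und <- matrix(undistorted, ncol = 2L)
  dst <- matrix(distorted, ncol = 2L)
  if (nrow(und) < 6L) stop("need at least 6 point pairs")
  r2 <- rowSums(sweep(und, 2L, center)^2) / normRadius^2
  if (diff(range(r2[r2 > 1e-12])) < 1e-9)
    stop("rank deficiency: all points lie at a single radius")
  resid <- function(k) {
    m <- distortionModel(k, center, normRadius)
    as.numeric(applyDistortion(und, m) - dst)
  }
  fit <- minpack.lm::nls.lm(par = c(0, 0, 0), fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  model <- distortionModel(fit$par, center, normRadius)
  rr <- resid(fit$par)
  list(model = model, rms = sqrt(mean(rr^2)),
       residuals = matrix(rr, ncol = 2L))
}

#' Classify the distortion type from coefficient signs
#'
#' Negative coefficients indicate barrel distortion, positive pincushion,
#' and a mix of signs mustache distortion; a model with all coefficients
#' (near) zero is undistorted.
#'
#' @param model a [DistortionModel-class] (or a length-3 coefficient
#'   vector).
#' @param tol magnitude below which a coefficient counts as zero.
#' @return one of `"none"`, `"barrel"`, `"pincushion"`, `"mustache"`.
#' @examples
#' classifyDistortion(distortionModel(c(0.1, -0.02, 0)))  # "mustache"
#' @export
classifyDistortion <- function(model, tol = 1e-8) {
  k <- if (is(model, "DistortionModel")) model@k else as.numeric(model)
  k <- k[abs(k) > tol]
  if (!length(k)) return("none")
  if (all(k > 0)) return("pincushion")
  if (all(k < 0)) return("barrel")
  "mustache"
}
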