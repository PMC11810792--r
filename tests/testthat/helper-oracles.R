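## Independent oracles and fixture builders used across the suite.

## DTW by exhaustive recursive path enumeration (steps down/right/diag,
## |a-b| cost, unnormalized) -- independent of the package implementation.
dtwOracle <- function(a, b) {
  rec <- function(i, j) {
    cc <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(cc)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    cc + best
  }
  rec(length(a), length(b))
}

## NNLS by exhaustive enumeration of all active sets (single RHS vector).
nnlsOracle <- function(A, b) {
  n <- ncol(A)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    P <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    x <- numeric(n)
    if (any(P)) {
      Ap <- A[, P, drop = FALSE]
      sol <- tryCatch(solve(crossprod(Ap), crossprod(Ap, b)),
                      error = function(e) NULL)
      if (is.null(sol)) next
      x[P] <- sol
    }
    if (any(x < -1e-9)) next
    ss <- sum((b - A %*% x)^2)
    if (is.null(best) || ss < best$ss - 1e-12) best <- list(x = x, ss = ss)
  }
  best$x
}

## smooth pseudo-random image for registration fixtures
smoothImage <- function(h, w, seed = 1, sigma = 2) {
  set.seed(seed)
  m <- matrix(rnorm(h * w), h, w)
  k <- calciumvr:::.gaussKernel(sigma)
  for (i in seq_len(h)) m[i, ] <- calciumvr:::.gaussSmooth(m[i, ], sigma)
  for (j in seq_len(w)) m[, j] <- calciumvr:::.gaussSmooth(m[, j], sigma)
  m
}

## exact subpixel shift via Fourier phase ramp (content moves +dy, +dx)
fourierShift <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  fy <- c(0:floor((h - 1) / 2), -(ceiling((h - 1) / 2):1)) / h
  fx <- c(0:floor((w - 1) / 2), -(ceiling((w - 1) / 2):1)) / w
  ph <- exp(-2i * pi * (outer(fy * dy, rep(1, w)) +
                          outer(rep(1, h), fx * dx)))
  Re(fft(fft(m) * ph, inverse = TRUE)) / (h * w)
}

## build an AlignedResponses object directly from a planted array
makeAligned <- function(resp, labels, rate = 14.31, velocity = NULL) {
  nt <- dim(resp)[2L]
  if (is.null(velocity)) velocity <- matrix(0, nt, dim(resp)[3L])
  new("AlignedResponses", responses = resp,
      time = (-(nt - 1L):0) / rate, labels = labels, velocity = velocity,
      preWindow = nt / rate, rate = rate,
      trialInfo = data.frame(row.names = seq_len(dim(resp)[3L])))
}

## cosine-similarity matrix between factor columns
congruence <- function(U, V) {
  Un <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  Vn <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  crossprod(Un, Vn)
}

## best per-component min-over-modes congruence over column permutations
matchFactors <- function(fit, truth) {
  R <- ncol(truth$A)
  cA <- congruence(truth$A, factorMatrix(fit, "neuron"))
  cB <- congruence(truth$B, factorMatrix(fit, "time"))
  cC <- congruence(truth$C, factorMatrix(fit, "trial"))
  allPerms <- function(v) if (length(v) == 1) list(v) else {
    out <- list()
    for (i in seq_along(v))
      for (p in allPerms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- NULL
  for (p in allPerms(seq_len(R))) {
    sc <- vapply(seq_len(R), function(r)
      min(cA[r, p[r]], cB[r, p[r]], cC[r, p[r]]), numeric(1))
    if (is.null(best) || min(sc) > min(best)) best <- sc
  }
  best
}

## small standard config used in many tests
testConfig <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed, nNeurons = 6L, gridShape = c(2L, 3L),
                   nTrialsPerZone = 5L)
  do.call(simConfig, utils::modifyList(defaults, args))
}
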