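## Non-negative CP (tensor component) analysis via alternating NNLS with
## block principal pivoting.

## truncated, normalized Gaussian kernel and reflect-padded smoothing
.gaussKernel <- function(sigmaSamp) {
  if (sigmaSamp <= 0) return(1)
  r <- max(1L, ceiling(3 * sigmaSamp))
  k <- exp(-((-r:r)^2) / (2 * sigmaSamp^2))
  k / sum(k)
}

.gaussSmooth <- function(x, sigmaSamp) {
  k <- .gaussKernel(sigmaSamp)
  if (length(k) == 1L) return(x)
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  pad <- c(x[pmin(r:1, n)], x, x[pmax(n - (1:r) + 1L, 1L)])
  as.numeric(stats::filter(pad, k, sides = 2L))[(r + 1L):(r + n)]
}

#' Build the trial tensor for tensor component analysis
#'
#' Gaussian-filters the aligned transients along time (truncated kernel,
#' reflect padding), crops to the last `crop` seconds before the zone end,
#' clips negative dF/F at zero (non-negativity required by the
#' decomposition; a shift-to-minimum alternative is available), and
#' attaches the per-trial motion integral.
#'
#' @param aligned an [AlignedResponses-class] with `preWindow >= crop`.
#' @param crop window length before the zone end (s).
#' @param sigma Gaussian filter sigma (s); 0 disables filtering.
#' @param negatives `"clip"` (default) or `"shift"` (subtract the minimum).
#' @return list of class `"TrialTensor"`: `data` (neurons x time x trials,
#'   all entries >= 0), `time`, `labels`, `motion` (per-trial velocity
#'   integral over the cropped window), `sigma`.
#' @export
buildTensor <- function(aligned, crop = 5, sigma = 0.15,
                        negatives = c("clip", "shift")) {
  negatives <- match.arg(negatives)
  resp <- aligned@responses
  if (anyNA(resp)) {
    badTr <- which(apply(resp, 3L, anyNA))
    stop("NaN in input for trial(s): ", paste(badTr, collapse = ", "))
  }
  if (aligned@preWindow < crop - 1e-9)
    stop("aligned preWindow must be at least the crop length")
  rate <- aligned@rate
  sigmaSamp <- sigma * rate
  if (sigmaSamp > 0) {
    for (i in seq_len(dim(resp)[1L]))
      for (k in seq_len(dim(resp)[3L]))
        resp[i, , k] <- .gaussSmooth(resp[i, , k], sigmaSamp)
  }
  nsamp <- round(crop * rate)
  nt <- dim(resp)[2L]
  sel <- (nt - nsamp + 1L):nt
  resp <- resp[, sel, , drop = FALSE]
  resp <- if (negatives == "clip") pmax(resp, 0) else resp - min(resp)
  motion <- colSums(aligned@velocity[sel, , drop = FALSE]) / rate
  structure(list(data = resp, time = aligned@time[sel],
                 labels = aligned@labels, motion = motion, sigma = sigma),
            class = "TrialTensor")
}

#' Non-negativity-constrained least squares by block principal pivoting
#'
#' Solves `min ||A X - B||_F` subject to `X >= 0`, column by column, with
#' the block principal pivoting active-set exchange: all KKT-violating
#' variables are exchanged between the passive and active sets at once,
#' with a backup rule (shrinking full exchanges, then single-variable
#' exchange of the largest index) guaranteeing finite termination.  The
#' returned solution satisfies the exact KKT conditions of the constrained
#' problem; whenever the unconstrained solution is already non-negative it
#' is returned unchanged.
#'
#' @param A m x n design matrix (full column rank; otherwise a small ridge
#'   is added with a warning).
#' @param B m x k right-hand side (vector or matrix).
#' @param tol KKT feasibility tolerance.
#' @return n x k non-negative solution matrix.
#' @examples
#' nnlsBPP(diag(2), c(3, 1))     # 3, 1
#' nnlsBPP(matrix(2), -4)        # 0 (constraint binds)
#' @export
nnlsBPP <- function(A, B, tol = 1e-12) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- ncol(A)
  AtA <- crossprod(A)
  if (rcond(AtA) < 1e-12) {
    warning("design matrix is (near) rank deficient; adding ridge regularization")
    AtA <- AtA + diag(1e-10 * max(diag(AtA), 1), n)
  }
  AtB <- crossprod(A, B)
  X <- matrix(0, n, ncol(B))
  for (j in seq_len(ncol(B))) {
    atb <- AtB[, j]
    P <- rep(FALSE, n)
    x <- numeric(n)
    y <- -atb
    p <- 3L; ninf <- n + 1L
    iter <- 0L
    repeat {
      V <- (!P & y < -tol) | (P & x < -tol)
      if (!any(V)) break
      iter <- iter + 1L
      if (iter > 50L * n) {                 # safeguard; backup rule should prevent this
        V <- which(V); V <- V[length(V)]
        P[V] <- !P[V]
      } else if (sum(V) < ninf) {
        ninf <- sum(V); p <- 3L
        P[V] <- !P[V]
      } else if (p > 0L) {
        p <- p - 1L
        P[V] <- !P[V]
      } else {
        v <- max(which(V))                  # single exchange, largest index
        P[v] <- !P[v]
      }
      x <- numeric(n); y <- numeric(n)
      if (any(P)) {
        x[P] <- solve(AtA[P, P, drop = FALSE], atb[P])
        y[!P] <- AtA[!P, P, drop = FALSE] %*% x[P] - atb[!P]
      } else {
        y <- -atb
      }
    }
    x[x < 0] <- 0
    X[, j] <- x
  }
  X
}

.khatriRao <- function(C, B) {
  ## rows ordered with B's index fastest
  C[rep(seq_len(nrow(C)), each = nrow(B)), , drop = FALSE] *
    B[rep(seq_len(nrow(B)), nrow(C)), , drop = FALSE]
}

.colNorms <- function(M) {
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  nrm
}

#' Non-negative CP decomposition of a trial tensor
#'
#' Alternating optimization of the neuron, temporal and trial factor
#' matrices of a rank-`rank` canonical polyadic model, each update solved
#' exactly by non-negativity-constrained least squares with block principal
#' pivoting on the matricized problem.  Iterations stop when the relative
#' reconstruction error changes by less than `tol` or after `maxIter`
#' iterations; the best of `nRestarts` random restarts is kept.  The
#' objective is non-increasing across iterations.  Neuron and time factor
#' columns are unit L2-normalized with the scale absorbed into the trial
#' factors.
#'
#' @param tensor a `TrialTensor` (from [buildTensor()]) or a non-negative
#'   3D array.
#' @param rank number of components (>= 1).
#' @param nRestarts random restarts.
#' @param seed RNG seed; results are deterministic given the seed.
#' @param maxIter iteration cap per restart.
#' @param tol relative-error change threshold.
#' @return a [CPFactors-class].
#' @export
cpDecomposeNonneg <- function(tensor, rank, nRestarts = 3, seed = 1,
                              maxIter = 500, tol = 1e-6) {
  X <- if (inherits(tensor, "TrialTensor")) tensor$data else tensor
  if (rank < 1L) stop("rank must be >= 1")
  dI <- dim(X)[1L]; dJ <- dim(X)[2L]; dK <- dim(X)[3L]
  normX <- sqrt(sum(X^2))
  if (normX == 0) {
    out <- new("CPFactors", neuron = matrix(0, dI, rank),
               time = matrix(0, dJ, rank), trial = matrix(0, dK, rank),
               rank = as.integer(rank), error = 0,
               objective = 0, converged = TRUE)
    attr(out, "zeroTensor") <- TRUE
    return(out)
  }
  X1 <- matrix(X, dI)                              # I x (J*K), j fastest
  X2 <- matrix(aperm(X, c(2L, 1L, 3L)), dJ)        # J x (I*K), i fastest
  X3 <- matrix(aperm(X, c(3L, 1L, 2L)), dK)        # K x (I*J), i fastest
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    B <- matrix(runif(dJ * rank), dJ)
    C <- matrix(runif(dK * rank), dK)
    A <- matrix(0, dI, rank)
    objTrace <- numeric(0)
    errPrev <- Inf
    converged <- FALSE
    revivals <- 0L
    for (it in seq_len(maxIter)) {
      ## transient zero columns make the Khatri-Rao product rank deficient;
      ## the ridge fallback bridges the update until the revival rule fires
      A <- t(suppressWarnings(nnlsBPP(.khatriRao(C, B), t(X1))))
      B <- t(suppressWarnings(nnlsBPP(.khatriRao(C, A), t(X2))))
      C <- t(suppressWarnings(nnlsBPP(.khatriRao(B, A), t(X3))))
      ## a component whose column zeroes out in any mode is dead: revive it
      ## with fresh random draws (objective restarts from the revival)
      dead <- colSums(A) == 0 | colSums(B) == 0 | colSums(C) == 0
      if (any(dead) && revivals < 5L && it < maxIter - 5L) {
        for (rr in which(dead)) {
          A[, rr] <- runif(dI); B[, rr] <- runif(dJ); C[, rr] <- runif(dK)
        }
        revivals <- revivals + 1L
        objTrace <- numeric(0)
        errPrev <- Inf
        next
      }
      recon <- A %*% t(.khatriRao(C, B))
      err <- sqrt(sum((X1 - recon)^2)) / normX
      objTrace <- c(objTrace, err)
      if (abs(errPrev - err) < tol) { converged <- TRUE; break }
      errPrev <- err
    }
    if (is.null(best) || err < best$err)
      best <- list(A = A, B = B, C = C, err = err, obj = objTrace,
                   converged = converged)
  }
  nA <- .colNorms(best$A); nB <- .colNorms(best$B)
  A <- sweep(best$A, 2L, nA, "/")
  B <- sweep(best$B, 2L, nB, "/")
  C <- sweep(best$C, 2L, nA * nB, "*")
  new("CPFactors", neuron = A, time = B, trial = C,
      rank = as.integer(rank), error = best$err, objective = best$obj,
      converged = best$converged)
}

#' Interpret CP components
#'
#' Per component: Pearson correlation of the trial factor with the
#' per-trial motion integral; aversive-versus-control two-sample tests on
#' the trial factors (both t-test and Mann-Whitney reported); and a kinetic
#' tag from the temporal factor (`"ramp"` for a monotone rise peaking at
#' the zone end, `"ON"` for an early peak, `"other"` otherwise).
#'
#' @param factors a [CPFactors-class].
#' @param motion per-trial motion integrals.
#' @param labels per-trial zone classes (`"AVER"`/`"CTRL"`).
#' @return data.frame with one row per component: `motionR`, `pT`,
#'   `pMW`, `kinetics`, `zeroTrial` flag.
#' @export
interpretFactors <- function(factors, motion, labels) {
  K <- factors@rank
  tf <- factors@trial
  if (nrow(tf) != length(motion) || nrow(tf) != length(labels))
    stop("motion and labels must align with the trial factors")
  out <- data.frame(component = seq_len(K), motionR = NA_real_,
                    pT = NA_real_, pMW = NA_real_,
                    kinetics = NA_character_, zeroTrial = FALSE)
  nt <- nrow(factors@time)
  for (k in seq_len(K)) {
    v <- tf[, k]
    if (all(v == 0)) { out$zeroTrial[k] <- TRUE } else {
      if (sd(v) > 0 && sd(motion) > 0) out$motionR[k] <- cor(v, motion)
      a <- v[labels == "AVER"]; c0 <- v[labels == "CTRL"]
      if (length(a) >= 2L && length(c0) >= 2L) {
        out$pT[k] <- tryCatch(t.test(a, c0)$p.value,
                              error = function(e) NA_real_)
        out$pMW[k] <- suppressWarnings(wilcox.test(a, c0)$p.value)
      }
    }
    w <- factors@time[, k]
    pk <- which.max(w)
    rising <- suppressWarnings(cor(w, seq_len(nt), method = "spearman"))
    out$kinetics[k] <- if (pk >= 0.85 * nt && isTRUE(rising > 0.7)) "ramp"
    else if (pk <= 0.3 * nt) "ON" else "other"
  }
  out
}

#' Rank selection by cross-trial-split reconstruction error
#'
#' Fits each candidate rank on a random half of the trials and evaluates
#' the reconstruction error on the held-out trials (trial factors refitted
#' by NNLS with neuron/time factors frozen); picks the rank with the lowest
#' held-out error, the operational form of the requirement that components
#' do not overfit.
#'
#' @param tensor a `TrialTensor` or 3D array.
#' @param ranks candidate ranks.
#' @param seed RNG seed.
#' @param ... passed to [cpDecomposeNonneg()].
#' @return list with `rank`, `trainError`, `testError`.
#' @export
selectRank <- function(tensor, ranks = 1:8, seed = 1, ...) {
  X <- if (inherits(tensor, "TrialTensor")) tensor$data else tensor
  dK <- dim(X)[3L]
  set.seed(seed)
  train <- sort(sample.int(dK, ceiling(dK / 2)))
  test <- setdiff(seq_len(dK), train)
  trainErr <- testErr <- numeric(length(ranks))
  Xte <- matrix(X[, , test, drop = FALSE], dim(X)[1L] * dim(X)[2L],
                length(test))
  for (i in seq_along(ranks)) {
    fit <- cpDecomposeNonneg(X[, , train, drop = FALSE], ranks[i],
                             seed = seed + i, ...)
    trainErr[i] <- fit@error
    M <- .khatriRao(fit@time, fit@neuron)   # (I*J) x R, i fastest
    Cte <- nnlsBPP(M, Xte)
    testErr[i] <- sqrt(sum((Xte - M %*% Cte)^2)) / sqrt(sum(Xte^2))
  }
  list(rank = ranks[which.min(testErr)], trainError = trainErr,
       testError = testErr)
}
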