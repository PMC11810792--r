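## Zone-end alignment and learning quantities: ramp amplitude, activation
## ratio, zone preference, reinforcement decomposition.

#' Align dF/F transients to zone ends
#'
#' Cuts per-trial segments of `preWindow` seconds ending at the zone exit
#' (time 0), with the running speed resampled to the imaging rate and
#' aligned identically.  For aversive trials the end can be capped at the
#' scheduled first airpuff (`capAtPuff = TRUE`), the convention used when
#' quantifying learning so the airpuff's direct effect is excluded.  The
#' last sample is the frame at or before the end time (right-closed
#' convention); trials shorter than the available recording are dropped
#' with a reported count.
#'
#' @param dffMat neurons x frames dF/F matrix.
#' @param session a [SessionLog-class].
#' @param preWindow window length (s).
#' @param rate imaging rate (Hz).
#' @param capAtPuff cap aversive trial ends at the scheduled first airpuff.
#' @param zones zone classes to keep (default both).
#' @return an [AlignedResponses-class]; attribute `dropped` counts trials
#'   whose window ran past the start of the recording.
#' @export
alignToZoneEnd <- function(dffMat, session, preWindow = 5,
                           rate = 14.31, capAtPuff = FALSE,
                           zones = c("AVER", "CTRL")) {
  tr <- session@trials
  tr <- tr[tr$class %in% zones, , drop = FALSE]
  nf <- ncol(dffMat)
  tf <- (seq_len(nf) - 1L) / rate
  nsamp <- round(preWindow * rate)
  tv <- session@velocity
  segs <- list(); labs <- character(); vels <- list(); keptInfo <- list()
  dropped <- 0L
  for (i in seq_len(nrow(tr))) {
    endTime <- tr$exit[i]
    if (capAtPuff && tr$class[i] == "AVER")
      endTime <- min(endTime, tr$scheduledPuff[i])
    iEnd <- findInterval(endTime + 1e-9, tf)
    idx <- (iEnd - nsamp + 1L):iEnd
    if (idx[1L] < 1L || iEnd > nf) { dropped <- dropped + 1L; next }
    segs[[length(segs) + 1L]] <- dffMat[, idx, drop = FALSE]
    labs <- c(labs, tr$class[i])
    vels[[length(vels) + 1L]] <-
      approx(tv$time, tv$velocity, xout = tf[idx], rule = 2)$y
    keptInfo[[length(keptInfo) + 1L]] <- tr[i, , drop = FALSE]
  }
  if (!length(segs)) stop("no trial long enough for the requested window")
  resp <- array(NA_real_, dim = c(nrow(dffMat), nsamp, length(segs)))
  for (k in seq_along(segs)) resp[, , k] <- segs[[k]]
  velM <- do.call(cbind, vels)
  info <- do.call(rbind, keptInfo)
  rownames(info) <- NULL
  out <- new("AlignedResponses", responses = resp,
             time = (-(nsamp - 1L):0) / rate, labels = labs,
             velocity = velM, preWindow = preWindow, rate = rate,
             trialInfo = info)
  attr(out, "dropped") <- dropped
  out
}

.windowIdx <- function(time, window) {
  sel <- which(time >= window[1L] - 1e-9 & time <= window[2L] + 1e-9)
  if (!length(sel)) stop("empty window after discretization")
  sel
}

#' Ramp-like amplitude at zone ends
#'
#' Amplitude of the ramp-like component: the time-integral of dF/F over the
#' window before the zone end divided by the window length (i.e. the window
#' mean), per neuron and per trial.  Reporting the mean makes the two
#' conventional windows, (-1, -0.4) s and (-1, -0.3) s, directly
#' comparable; a raw-integral mode is retained.
#'
#' @param aligned an [AlignedResponses-class].
#' @param window integration window (s, s), start < end <= 0.
#' @param mode `"mean"` (default) or `"integral"`.
#' @return list of class `"RampTable"`: `perTrial` (neurons x trials),
#'   `perNeuron` (trial-averaged), `perNeuronAver`/`perNeuronCtrl`
#'   (zone-wise trial averages), `window`, `mode`.
#' @export
rampAmplitude <- function(aligned, window = c(-1, -0.4),
                          mode = c("mean", "integral")) {
  mode <- match.arg(mode)
  if (window[1L] >= window[2L] || window[2L] > 0)
    stop("window must satisfy start < end <= 0")
  sel <- .windowIdx(aligned@time, window)
  resp <- aligned@responses
  perTrial <- apply(resp[, sel, , drop = FALSE], c(1L, 3L), mean)
  if (mode == "integral") perTrial <- perTrial * (window[2L] - window[1L])
  labs <- aligned@labels
  structure(list(
    perTrial = perTrial,
    perNeuron = rowMeans(perTrial),
    perNeuronAver = rowMeans(perTrial[, labs == "AVER", drop = FALSE]),
    perNeuronCtrl = rowMeans(perTrial[, labs == "CTRL", drop = FALSE]),
    window = window, mode = mode), class = "RampTable")
}

#' Fraction of activated neurons
#'
#' A neuron is active when its response-window dF/F exceeds its baseline.
#' `threshold_2sem`: the trial-mean response must exceed the baseline mean
#' plus twice the baseline's standard error across trials.  `paired_t` /
#' `paired_wilcoxon`: one-tailed paired test of response versus baseline
#' across trials at level `alpha`.  Fractions are reported raw and (for the
#' test methods) Benjamini-Hochberg adjusted.
#'
#' @param aligned an [AlignedResponses-class] (>= 2 trials).
#' @param baselineWindow baseline window (s, s) on the aligned axis; choose
#'   a `preWindow` long enough that it precedes the ramp onset.
#' @param responseWindow response window (s, s).
#' @param method `"threshold_2sem"`, `"paired_t"` or `"paired_wilcoxon"`.
#' @param alpha test level.
#' @return list with `fraction`, `active` (per-neuron flags), `pvalues`
#'   (NA for the threshold method), `fractionAdjusted`.
#' @export
activationRatio <- function(aligned, baselineWindow = NULL,
                            responseWindow = c(-1, -0.4),
                            method = c("threshold_2sem", "paired_t",
                                       "paired_wilcoxon"),
                            alpha = 0.05) {
  method <- match.arg(method)
  nTrials <- dim(aligned@responses)[3L]
  if (nTrials < 2L) stop("need at least 2 trials")
  if (is.null(baselineWindow))
    baselineWindow <- c(min(aligned@time), min(aligned@time) + 1)
  bi <- .windowIdx(aligned@time, baselineWindow)
  ri <- .windowIdx(aligned@time, responseWindow)
  base <- apply(aligned@responses[, bi, , drop = FALSE], c(1L, 3L), mean)
  resp <- apply(aligned@responses[, ri, , drop = FALSE], c(1L, 3L), mean)
  n <- nrow(base)
  pv <- rep(NA_real_, n)
  if (method == "threshold_2sem") {
    sem <- apply(base, 1L, sd) / sqrt(nTrials)
    active <- rowMeans(resp) > rowMeans(base) + 2 * sem
    fracAdj <- NA_real_
  } else {
    for (i in seq_len(n)) {
      pv[i] <- if (method == "paired_t")
        t.test(resp[i, ], base[i, ], paired = TRUE,
               alternative = "greater")$p.value
      else suppressWarnings(
        wilcox.test(resp[i, ], base[i, ], paired = TRUE,
                    alternative = "greater")$p.value)
    }
    active <- pv < alpha
    fracAdj <- mean(p.adjust(pv, "BH") < alpha)
  }
  list(fraction = mean(active), active = active, pvalues = pv,
       fractionAdjusted = fracAdj)
}

#' Classify per-neuron zone preference
#'
#' Per neuron, the difference between the mean aversive-zone and mean
#' control-zone ramp amplitude is tested across trials (two-tailed
#' two-sample t-test at level `alpha`); neurons passing are labeled by the
#' sign of the difference, the rest `"none"`.  Population fractions are
#' reported.
#'
#' @param aligned an [AlignedResponses-class] with both zone labels.
#' @param window ramp window (s, s).
#' @param alpha test level.
#' @return list with `labels` (per neuron: `"AVER-coding"`,
#'   `"CTRL-coding"`, `"none"`), `difference`, `pvalues`, `fractions`.
#' @export
classifyZonePreference <- function(aligned, window = c(-1, -0.4),
                                   alpha = 0.05) {
  labs <- aligned@labels
  if (!all(c("AVER", "CTRL") %in% labs))
    stop("both zone labels must be present")
  rt <- rampAmplitude(aligned, window)
  pt <- rt$perTrial
  n <- nrow(pt)
  lab <- rep("none", n)
  pv <- numeric(n)
  dif <- rt$perNeuronAver - rt$perNeuronCtrl
  for (i in seq_len(n)) {
    a <- pt[i, labs == "AVER"]; c0 <- pt[i, labs == "CTRL"]
    pv[i] <- tryCatch(t.test(a, c0)$p.value, error = function(e) NA_real_)
    if (is.finite(pv[i]) && pv[i] < alpha)
      lab[i] <- if (dif[i] > 0) "AVER-coding" else "CTRL-coding"
  }
  list(labels = lab, difference = dif, pvalues = pv,
       fractions = c(AVER = mean(lab == "AVER-coding"),
                     CTRL = mean(lab == "CTRL-coding"),
                     none = mean(lab == "none")))
}

#' Decompose reinforcement responses into two components
#'
#' Poor-learner neurons show a monocomponent reinforcement response, well
#' fitted by a single exponential that overlaps the normalized running
#' speed; good learners carry an additional second component after
#' reinforcement.  Operationally: the post-airpuff response is fitted by
#' nonnegative least squares with an exponential-decay regressor (time
#' constant profiled over a grid) plus the normalized velocity; the first
#' component is this fitted part and the second component is the
#' time-integral of the nonnegative residual.  Per-component velocity
#' correlations are reported.
#'
#' Because the second component sits on top of the first, an ordinary
#' least-squares fit would absorb part of it into the exponential; the
#' first-component fit is therefore iteratively trimmed: samples whose
#' residual exceeds twice the spread of the negative residuals are treated
#' as belonging to the second component and excluded from the refit, until
#' the support stabilizes.
#'
#' @param resp neurons x time matrix aligned to the first airpuff (t = 0 at
#'   the first column).
#' @param vel velocity aligned identically (length = ncol(resp)).
#' @param rate sampling rate (Hz); the post-airpuff window must span at
#'   least 3 s.
#' @param tauGrid candidate decay time constants (s).
#' @param minSupport smallest fraction of samples the trimmed fit may keep.
#' @return data.frame of class `"ReinforcementDecomposition"`: `firstAmp`,
#'   `tau`, `velGain`, `secondComponent`, `corFirstVel`, `corSecondVel`.
#' @export
decomposeReinforcement <- function(resp, vel, rate,
                                   tauGrid = seq(0.2, 3, by = 0.1),
                                   minSupport = 0.5) {
  nt <- ncol(resp)
  if (nt / rate < 3) stop("post-airpuff window must span at least 3 s")
  if (length(vel) != nt) stop("velocity must match the response time axis")
  tt <- (seq_len(nt) - 1L) / rate
  vn <- vel - min(vel)
  if (max(vn) > 0) vn <- vn / max(vn)
  dt <- 1 / rate
  n <- nrow(resp)
  out <- data.frame(firstAmp = numeric(n), tau = NA_real_,
                    velGain = numeric(n), secondComponent = numeric(n),
                    corFirstVel = NA_real_, corSecondVel = NA_real_)
  for (i in seq_len(n)) {
    y <- resp[i, ]
    if (all(abs(y) < 1e-12)) next
    best <- NULL
    useVel <- max(vn) > 0
    nS <- length(y)
    for (tau in tauGrid) {
      X <- if (useVel) cbind(exp(-tt / tau), vn) else cbind(exp(-tt / tau))
      mask <- rep(TRUE, nS)
      cf <- nnlsBPP(X, matrix(y, ncol = 1L))
      for (trim in seq_len(10L)) {
        r <- y - as.numeric(X %*% cf)
        spread <- sd(r[r <= 0])
        if (!is.finite(spread)) spread <- 0
        newMask <- r <= pmax(2 * spread, 1e-8)
        if (mean(newMask) < minSupport)
          newMask <- r <= quantile(r, minSupport)
        if (identical(newMask, mask)) break
        mask <- newMask
        cf <- nnlsBPP(X[mask, , drop = FALSE],
                      matrix(y[mask], ncol = 1L))
      }
      r <- y - as.numeric(X %*% cf)
      ss <- mean(r[mask]^2)
      if (is.null(best) || ss < best$ss)
        best <- list(ss = ss, tau = tau, cf = cf, fit = as.numeric(X %*% cf))
    }
    residual <- y - best$fit
    second <- pmax(residual, 0)
    out$firstAmp[i] <- best$cf[1L]
    out$tau[i] <- best$tau
    out$velGain[i] <- if (useVel) best$cf[2L] else 0
    out$secondComponent[i] <- sum(second) * dt
    if (sd(best$fit) > 0 && sd(vel) > 0)
      out$corFirstVel[i] <- cor(best$fit, vel)
    if (sd(second) > 0 && sd(vel) > 0)
      out$corSecondVel[i] <- cor(second, vel)
  }
  class(out) <- c("ReinforcementDecomposition", "data.frame")
  out
}

#' Correlate early reinforcement with late learning
#'
#' Pearson correlation (with least-squares slope) between the
#' second-component reinforcement amplitudes measured early in learning and
#' the ramp amplitudes measured late, across the same neurons.
#'
#' @param second early-phase second-component amplitudes, one per neuron.
#' @param ramp late-phase ramp amplitudes, same neurons.
#' @return list with `r`, `slope`, `p`.
#' @export
correlateLearning <- function(second, ramp) {
  if (length(second) != length(ramp))
    stop("inputs must cover the same neuron set")
  if (length(second) < 3L) stop("need at least 3 neurons")
  ct <- stats::cor.test(second, ramp)
  list(r = unname(ct$estimate),
       slope = unname(coef(lm(ramp ~ second))[2L]),
       p = ct$p.value)
}
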