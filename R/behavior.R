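## Behavioral statistics: abyss-test metrics, DTW-bootstrap learning score,
## anticipatory licking, Gaussian velocity-distribution fit.

#' Dynamic time warping distance
#'
#' Classical accumulated-cost DTW with absolute-difference local cost, the
#' symmetric step pattern (down, right, diagonal), no window constraint and
#' no normalization.  `dtwDistance(a, a) == 0` and the distance is
#' symmetric.
#'
#' @param a,b nonempty numeric series.
#' @return nonnegative accumulated cost.
#' @examples
#' dtwDistance(c(0, 1), c(1, 0))  # 2
#' @export
dtwDistance <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty input series")
  dtw_cost(as.numeric(a), as.numeric(b))
}

#' Detect the abyss edge event of a run
#'
#' The edge time is the first moment the mouse passes the spatial coordinate
#' of the cliff edge; if the edge is never passed, it is the beginning of
#' the first period of at least `stopWindow` seconds of standstill at a
#' position from which the edge is already visible.  If neither happens
#' within `timeout` seconds the run is a failed trial.
#'
#' @param trace data.frame with `time`, `velocity`, `position`.
#' @param edgeCoord edge position (corridor units).
#' @param visibilityCoord position from which the edge is visible
#'   (`<= edgeCoord`).
#' @param timeout seconds before the trial is marked failed.
#' @param stopWindow minimum standstill duration (s).
#' @param stopThresh |velocity| below which the mouse counts as stopped.
#' @return list with `classification` (`"crossed"`, `"stopped_at_view"` or
#'   `"failed"`) and `edgeTime` (NA when failed).
#' @export
detectEdge <- function(trace, edgeCoord, visibilityCoord, timeout = 20,
                       stopWindow = 2, stopThresh = 0.5) {
  if (visibilityCoord > edgeCoord)
    stop("visibilityCoord must be <= edgeCoord")
  cross <- which(trace$position >= edgeCoord)
  if (length(cross) && trace$time[cross[1L]] <= timeout)
    return(list(classification = "crossed", edgeTime = trace$time[cross[1L]]))
  stopped <- abs(trace$velocity) <= stopThresh &
    trace$position >= visibilityCoord
  r <- rle(stopped)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- if (nrow(trace) > 1L) trace$time[2L] - trace$time[1L] else 0
  for (i in which(r$values)) {
    dur <- r$lengths[i] * dt
    t0 <- trace$time[starts[i]]
    if (dur >= stopWindow && t0 <= timeout)
      return(list(classification = "stopped_at_view", edgeTime = t0))
  }
  list(classification = "failed", edgeTime = NA_real_)
}

#' Velocity ratio at the abyss edge
#'
#' Ratio of the average velocity after versus before the edge moment, over
#' `window`-second intervals (2 s by default): slowing gives a ratio below
#' 1, a full stop 0, and recoil (negative velocity) a negative ratio.  The
#' orientation is switchable.
#'
#' @param trace data.frame with `time` and `velocity`.
#' @param edgeTime edge moment (s); the trace must cover
#'   `[edgeTime - window, edgeTime + window]`.
#' @param window interval length (s).
#' @param orientation `"after_before"` (default) or `"before_after"`.
#' @return list with `ratio` (NA and `flag = TRUE` when the reference mean
#'   is 0), `before`, `after`.
#' @export
velocityRatio <- function(trace, edgeTime, window = 2,
                          orientation = c("after_before", "before_after")) {
  orientation <- match.arg(orientation)
  if (is.na(edgeTime)) stop("edgeTime is undefined (failed trial)")
  if (edgeTime - window < min(trace$time) - 1e-9 ||
      edgeTime + window > max(trace$time) + 1e-9)
    stop("trace does not cover the +/- window around edgeTime")
  before <- mean(trace$velocity[trace$time >= edgeTime - window &
                                trace$time < edgeTime])
  after <- mean(trace$velocity[trace$time > edgeTime &
                               trace$time <= edgeTime + window])
  ref <- if (orientation == "after_before") before else after
  num <- if (orientation == "after_before") after else before
  if (ref == 0)
    return(list(ratio = NA_real_, before = before, after = after, flag = TRUE))
  list(ratio = num / ref, before = before, after = after, flag = FALSE)
}

#' Summarize a set of abyss runs
#'
#' Classifies each run, computes the edge velocity ratio for non-failed
#' runs, and tests before-versus-after speeds with an unpaired t-test
#' (failed trials excluded from the test).
#'
#' @param abyss output of [generateAbyssRuns()] (or an equivalent list).
#' @param ... passed to [detectEdge()].
#' @return list with `outcomes` (per-run data.frame), `meanRatio`,
#'   `nFailed`, `p` (unpaired t-test before vs after).
#' @export
abyssTest <- function(abyss, ...) {
  out <- lapply(abyss$runs, function(tr) {
    de <- detectEdge(tr, abyss$edgeCoord, abyss$visibilityCoord, ...)
    if (de$classification == "failed")
      return(data.frame(classification = "failed", edgeTime = NA,
                        ratio = NA, before = NA, after = NA))
    vr <- velocityRatio(tr, de$edgeTime)
    data.frame(classification = de$classification, edgeTime = de$edgeTime,
               ratio = vr$ratio, before = vr$before, after = vr$after)
  })
  outcomes <- do.call(rbind, out)
  ok <- !is.na(outcomes$ratio)
  p <- if (sum(ok) >= 2)
    t.test(outcomes$before[ok], outcomes$after[ok])$p.value else NA_real_
  list(outcomes = outcomes, meanRatio = mean(outcomes$ratio[ok]),
       nFailed = sum(outcomes$classification == "failed"), p = p)
}

#' Label-shuffle bootstrap learning score
#'
#' Compares the speed difference between control and aversive zones to
#' random fluctuations: the original statistic is the DTW distance between
#' the label-group mean velocity curves over the pre-airpuff window; the
#' label vector (control = 1, aversive = 2) is shuffled `nShuffles` times
#' and the score is the proportion of shuffled differences lower than the
#' original (ties counted half, so degenerate nulls stay at the 0.5 chance
#' level).
#'
#' @param curves trials x samples matrix of velocity curves cropped to the
#'   pre-airpuff window (see [trialVelocityCurves()]).
#' @param labels integer per trial, 1 = control, 2 = aversive (at least two
#'   of each).
#' @param nShuffles number of label shuffles (default 1000).
#' @param seed RNG seed.
#' @param statistic `"dtw"` (default) or `"mean"` (absolute difference of
#'   group-mean curves, a simpler variant).
#' @return list of class `"BootstrapResult"`: `originalDiff`,
#'   `shuffledDiffs`, `score`, `nShuffles`.
#' @export
bootstrapLearning <- function(curves, labels, nShuffles = 1000, seed = 1,
                              statistic = c("dtw", "mean")) {
  statistic <- match.arg(statistic)
  labels <- as.integer(labels)
  if (!all(labels %in% c(1L, 2L)) || length(unique(labels)) < 2L)
    stop("labels must contain both 1 (control) and 2 (aversive)")
  if (min(table(labels)) < 2L) stop("need at least 2 trials per label")
  if (nrow(curves) != length(labels))
    stop("one label per curve required")
  stat <- function(lab) {
    m1 <- colMeans(curves[lab == 1L, , drop = FALSE])
    m2 <- colMeans(curves[lab == 2L, , drop = FALSE])
    if (statistic == "dtw") dtwDistance(m1, m2) else abs(mean(m2) - mean(m1))
  }
  orig <- stat(labels)
  set.seed(seed)
  shuf <- vapply(seq_len(nShuffles), function(i) stat(sample(labels)),
                 numeric(1))
  score <- (sum(shuf < orig) + 0.5 * sum(shuf == orig)) / nShuffles
  structure(list(originalDiff = orig, shuffledDiffs = shuf, score = score,
                 nShuffles = nShuffles), class = "BootstrapResult")
}

#' Quarter-wise bootstrap over a training day
#'
#' Splits the session into four equal time parts and computes the bootstrap
#' learning score separately in each quarter.
#'
#' @param session a [SessionLog-class].
#' @param nShuffles shuffles per quarter.
#' @param seed RNG seed.
#' @param preWindow pre-airpuff window (s).
#' @return list of four `BootstrapResult`s (NA where a quarter lacks both
#'   labels or has fewer than 2 trials of one).
#' @export
bootstrapByQuarter <- function(session, nShuffles = 1000, seed = 1,
                               preWindow = 1.5) {
  tvc <- trialVelocityCurves(session, preWindow)
  edges <- seq(0, session@duration, length.out = 5L)
  lapply(seq_len(4L), function(q) {
    sel <- tvc$times >= edges[q] & tvc$times < edges[q + 1L]
    lab <- tvc$labels[sel]
    if (length(unique(lab)) < 2L || min(table(lab)) < 2L) return(NA)
    bootstrapLearning(tvc$curves[sel, , drop = FALSE], lab,
                      nShuffles = nShuffles, seed = seed + q)
  })
}

#' Anticipatory licking rate before zone entries
#'
#' Licks per second in the `windowPre`-second half-open interval
#' `[entry - windowPre, entry)` preceding each entry, averaged over entries
#' per zone type.
#'
#' @param licks lick event times (s).
#' @param zoneEntries named list of entry-time vectors, one per zone type
#'   (or a single numeric vector).
#' @param windowPre pre-entry window (s), > 0.
#' @return named numeric vector of rates (licks/s); `NA` with a warning for
#'   zone types without entries.
#' @export
anticipatoryLicking <- function(licks, zoneEntries, windowPre) {
  if (windowPre <= 0) stop("'windowPre' must be > 0")
  if (!is.list(zoneEntries)) zoneEntries <- list(zone = zoneEntries)
  vapply(zoneEntries, function(entries) {
    if (!length(entries)) {
      warning("no entries for a zone type; rate undefined")
      return(NA_real_)
    }
    counts <- vapply(entries, function(e)
      sum(licks >= e - windowPre & licks < e), numeric(1))
    mean(counts) / windowPre
  }, numeric(1))
}

#' Gaussian fit of the velocity frequency distribution
#'
#' Fits the peak model
#' `y = y0 + A / (w * (pi / (4 ln 2))^-0.5) * exp(-4 ln 2 (x - xc)^2 / w^2)`
#' to a frequency count of the velocity data by damped (Levenberg-
#' Marquardt) nonlinear least squares, confirming approximate normality of
#' the velocity distribution.  `w` is the full width at half maximum and
#' `xc` the center.
#'
#' @param velocities velocity samples (failed trials excluded), or NULL if
#'   `x`/`y` are given directly.
#' @param nbins number of histogram bins for the frequency count.
#' @param x,y optional precomputed bin centers and counts.
#' @return list of class `"GaussianFitResult"`: `y0`, `A`, `w`, `xc`, `r2`,
#'   `pvalues` (per parameter), `fitted`, `x`, `y`.
#' @export
fitVelocityGaussian <- function(velocities = NULL, nbins = 30,
                                x = NULL, y = NULL) {
  if (is.null(x) || is.null(y)) {
    hh <- graphics::hist(velocities, breaks = nbins, plot = FALSE)
    x <- hh$mids; y <- hh$counts
  }
  if (sum(y > 0) < 10L) stop("need at least 10 histogram bins with counts")
  fln <- 4 * log(2)
  model <- function(p, x)
    p[1L] + p[2L] / (p[3L] * (pi / fln)^-0.5) * exp(-fln * (x - p[4L])^2 / p[3L]^2)
  resid <- function(p) y - model(p, x)
  wt <- pmax(y, 0)
  mu <- sum(x * wt) / sum(wt)
  s <- sqrt(sum(wt * (x - mu)^2) / sum(wt))
  starts <- list(c(min(y), max(y) * 2.3548 * s, 2.3548 * s, mu),
                 c(0, sum(y) * diff(x[1:2]), 2 * s, mu),
                 c(median(y), max(y), s, x[which.max(y)]))
  best <- NULL
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid, lower = c(-Inf, -Inf, 1e-8, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best) || !is.finite(best$deviance))
    stop("Gaussian fit did not converge after restarts; check the frequency counts")
  p <- best$par
  fitted <- model(p, x)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  sm <- try(summary(best), silent = TRUE)
  pv <- if (!inherits(sm, "try-error"))
    setNames(sm$coefficients[, "Pr(>|t|)"], c("y0", "A", "w", "xc"))
  else setNames(rep(NA_real_, 4L), c("y0", "A", "w", "xc"))
  structure(list(y0 = p[1L], A = p[2L], w = p[3L], xc = p[4L], r2 = r2,
                 pvalues = pv, fitted = fitted, x = x, y = y),
            class = "GaussianFitResult")
}
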