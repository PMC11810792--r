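## Assembly-level analyses: hub-cell detection, spatial clustering,
## spontaneous cross-correlation, few-cell decoder, trial clustering,
## lead-lag.

#' Detect the jump in the ramp-amplitude distribution (hub cells)
#'
#' Sorts the per-neuron ramp amplitudes ascending and looks at the first
#' difference: the threshold is placed at the largest gap whose upper
#' element lies in the top quartile of ranks (the jump sits at the top of
#' the amplitude range).  The jump is accepted when that gap exceeds twice
#' the median first difference; otherwise a no-jump flag is set and the hub
#' set is empty.  Neurons above the threshold are hub cells.  The rule is
#' invariant under increasing affine transforms of the amplitudes.
#'
#' @param amplitudes per-neuron ramp amplitudes (>= 10 neurons).
#' @return list of class `"HubAssignment"`: `sorted`, `order`,
#'   `firstDerivative`, `jumpIndex` (gap position in the sorted vector),
#'   `threshold`, `hubIds`, `nonHubIds`, `noJump`.
#' @export
detectAmplitudeThreshold <- function(amplitudes) {
  n <- length(amplitudes)
  if (n < 10L) stop("need at least 10 neurons")
  o <- order(amplitudes)
  s <- amplitudes[o]
  d <- diff(s)
  cand <- which(seq_along(d) + 1L > 0.75 * n)   # gap's upper rank in top quartile
  gaps <- d[cand]
  medGap <- median(d)
  if (!length(gaps) || max(gaps) <= 2 * medGap) {
    return(structure(list(sorted = s, order = o, firstDerivative = d,
                          jumpIndex = NA_integer_, threshold = NA_real_,
                          hubIds = integer(0), nonHubIds = seq_len(n),
                          noJump = TRUE), class = "HubAssignment"))
  }
  j <- cand[which.max(gaps)]
  thr <- (s[j] + s[j + 1L]) / 2
  hubs <- o[(j + 1L):n]
  structure(list(sorted = s, order = o, firstDerivative = d, jumpIndex = j,
                 threshold = thr, hubIds = sort(hubs),
                 nonHubIds = sort(o[seq_len(j)]), noJump = FALSE),
            class = "HubAssignment")
}

.meanPairDist <- function(xyz) mean(stats::dist(xyz))

#' Spatial clustering of hub cells
#'
#' Compares the mean pairwise Euclidean distance among hub somata to a null
#' of random equal-size subsets of the coding population; spatially
#' clustered hubs give a normalized ratio below 1 and a small one-sided
#' permutation p-value.
#'
#' @param xyz neurons x 3 soma coordinates (micrometers).
#' @param hubIds hub neuron indices (>= 3).
#' @param codingIds coding-neuron indices the null subsets are drawn from.
#' @param nDraws number of random subsets.
#' @param seed RNG seed.
#' @return list with `hubMean`, `nullMean`, `ratio`, `p`, `nullDists`.
#' @export
hubSpatialClustering <- function(xyz, hubIds, codingIds, nDraws = 1000,
                                 seed = 1) {
  if (length(hubIds) < 3L) stop("need at least 3 hub cells")
  set.seed(seed)
  hubMean <- .meanPairDist(xyz[hubIds, , drop = FALSE])
  k <- length(hubIds)
  nulls <- vapply(seq_len(nDraws), function(i)
    .meanPairDist(xyz[sample(codingIds, k), , drop = FALSE]), numeric(1))
  list(hubMean = hubMean, nullMean = mean(nulls),
       ratio = hubMean / mean(nulls),
       p = (1 + sum(nulls <= hubMean)) / (nDraws + 1),
       nullDists = nulls)
}

#' Pairwise cross-correlation of spontaneous activity
#'
#' Zero-lag Pearson correlation between all neuron pairs restricted to
#' samples outside the aversive-zone intervals (spontaneous activity), with
#' group summaries for the hub set, the lowest-ramp group, and the rest.
#' Group means can be normalized to the maximum group.
#'
#' @param dffMat neurons x frames dF/F matrix.
#' @param rate imaging rate (Hz).
#' @param excludeIntervals matrix or data.frame with columns `start`, `end`
#'   (s) to exclude (aversive-zone visits).
#' @param hubIds,lowIds neuron index groups (lowest-ramp group optional).
#' @param normalize divide group means by the largest group mean.
#' @param minInclude minimum included time (s).
#' @return list with `matrix` (neurons x neurons), `groupMeans` (named:
#'   hub, low, rest), `normalized` (if requested), `includedSeconds`.
#' @export
spontaneousCrossCorr <- function(dffMat, rate, excludeIntervals = NULL,
                                 hubIds = integer(0), lowIds = integer(0),
                                 normalize = FALSE, minInclude = 30) {
  nf <- ncol(dffMat)
  tf <- (seq_len(nf) - 1L) / rate
  incl <- rep(TRUE, nf)
  if (!is.null(excludeIntervals) && NROW(excludeIntervals)) {
    ei <- as.data.frame(excludeIntervals)
    for (i in seq_len(nrow(ei)))
      incl[tf >= ei$start[i] & tf <= ei$end[i]] <- FALSE
  }
  if (sum(incl) / rate < minInclude)
    stop(sprintf("only %.1f s of included spontaneous activity (need %g s)",
                 sum(incl) / rate, minInclude))
  C <- suppressWarnings(cor(t(dffMat[, incl, drop = FALSE])))
  groupMean <- function(ids) {
    if (length(ids) < 2L) return(NA_real_)
    sub <- C[ids, ids]
    mean(sub[lower.tri(sub)], na.rm = TRUE)
  }
  rest <- setdiff(seq_len(nrow(dffMat)), union(hubIds, lowIds))
  gm <- c(hub = groupMean(hubIds), low = groupMean(lowIds),
          rest = groupMean(rest))
  out <- list(matrix = C, groupMeans = gm,
              includedSeconds = sum(incl) / rate)
  if (normalize) out$normalized <- gm / max(gm, na.rm = TRUE)
  out
}

#' Build and apply a few-cell trial decoder
#'
#' Selects the `k` neurons (3 to 7) with the largest aversive-minus-control
#' ramp-amplitude difference on the training trials; the decoder function
#' is their average dF/F, the decision statistic its window mean over
#' (-4, -2.5) s before the zone end, and the threshold the midpoint of the
#' training-class statistic means.  A held-out trial is labeled aversive
#' when its statistic exceeds the threshold.  With `k = NULL` the smallest
#' k in 3..7 reaching 100 percent training accuracy is used (else 7).
#'
#' @param aligned an [AlignedResponses-class] covering (-4, 0) s.
#' @param k number of member cells (3..7) or NULL for automatic selection.
#' @param window decision-statistic window (s, s).
#' @param rampWindow member-selection ramp window (s, s).
#' @param trainTrials indices of training trials; default: a random
#'   stratified half split.
#' @param seed RNG seed for the default split.
#' @return list of class `"Decoder"`: `members`, `k`, `window`,
#'   `threshold`, `trainTrials`, `testTrials`, `predicted` (held-out
#'   labels), `reliability`.
#' @export
buildDecoder <- function(aligned, k = NULL, window = c(-4, -2.5),
                         rampWindow = c(-1, -0.4), trainTrials = NULL,
                         seed = 1) {
  if (min(aligned@time) > window[1L] + 1e-9)
    stop("aligned window must cover the decision window")
  labs <- aligned@labels
  nTrials <- length(labs)
  if (is.null(trainTrials)) {
    set.seed(seed)
    trainTrials <- sort(c(sample(which(labs == "AVER"),
                                 ceiling(sum(labs == "AVER") / 2)),
                          sample(which(labs == "CTRL"),
                                 ceiling(sum(labs == "CTRL") / 2))))
  }
  testTrials <- setdiff(seq_len(nTrials), trainTrials)
  if (length(unique(labs[trainTrials])) < 2L || !length(testTrials))
    stop("degenerate train/test split: both labels required in training and a nonempty test set")
  if (!is.null(k) && (k < 3L || k > 7L)) stop("k must lie in 3..7")

  sel <- .windowIdx(aligned@time, rampWindow)
  amp <- apply(aligned@responses[, sel, , drop = FALSE], c(1L, 3L), mean)
  trLab <- labs[trainTrials]
  dif <- rowMeans(amp[, trainTrials[trLab == "AVER"], drop = FALSE]) -
    rowMeans(amp[, trainTrials[trLab == "CTRL"], drop = FALSE])
  rankIds <- order(dif, decreasing = TRUE)

  di <- .windowIdx(aligned@time, window)
  statFor <- function(members)
    apply(aligned@responses[members, di, , drop = FALSE], 3L, mean)
  fitK <- function(kk) {
    members <- rankIds[seq_len(kk)]
    st <- statFor(members)
    thr <- (mean(st[trainTrials[trLab == "AVER"]]) +
            mean(st[trainTrials[trLab == "CTRL"]])) / 2
    predTrain <- ifelse(st[trainTrials] > thr, "AVER", "CTRL")
    list(members = members, thr = thr, st = st,
         trainAcc = mean(predTrain == trLab))
  }
  if (is.null(k)) {
    fit <- NULL
    for (kk in 3:7) {
      fit <- fitK(kk)
      if (fit$trainAcc == 1) { k <- kk; break }
    }
    if (is.null(k)) k <- 7L
  } else fit <- fitK(k)
  pred <- ifelse(fit$st[testTrials] > fit$thr, "AVER", "CTRL")
  structure(list(members = fit$members, k = k, window = window,
                 threshold = fit$thr, trainTrials = trainTrials,
                 testTrials = testTrials, predicted = pred,
                 reliability = mean(pred == labs[testTrials])),
            class = "Decoder")
}

#' Cluster trials into high- and low-ramp groups
#'
#' 2-means clustering of the per-trial ramp scores (multiple seeded
#' restarts), plus the Pearson correlation between per-trial velocity
#' summaries and ramp scores, overall and per requested trial window.
#'
#' @param rampScores per-trial ramp scores (>= 6 trials).
#' @param velocity per-trial velocity summaries, same length.
#' @param windows optional named list of trial-index vectors over which the
#'   correlation is additionally reported.
#' @param seed RNG seed for the k-means restarts.
#' @return list of class `"TrialClassification"`: `labels`
#'   (`"high_ramp"`/`"low_ramp"`), `r` (overall), `rWindows`,
#'   `singleCluster` flag.
#' @export
clusterTrials <- function(rampScores, velocity, windows = NULL, seed = 1) {
  if (length(rampScores) < 6L) stop("need at least 6 trials")
  if (length(velocity) != length(rampScores))
    stop("velocity summaries must match the trials")
  if (sd(rampScores) == 0) {
    return(structure(list(labels = rep("low_ramp", length(rampScores)),
                          r = NA_real_, rWindows = NULL,
                          singleCluster = TRUE),
                     class = "TrialClassification"))
  }
  set.seed(seed)
  km <- kmeans(matrix(rampScores, ncol = 1L), centers = 2L, nstart = 10L)
  high <- which.max(km$centers)
  labels <- ifelse(km$cluster == high, "high_ramp", "low_ramp")
  rAll <- cor(velocity, rampScores)
  rW <- if (!is.null(windows))
    vapply(windows, function(ix) cor(velocity[ix], rampScores[ix]),
           numeric(1))
  structure(list(labels = labels, r = rAll, rWindows = rW,
                 singleCluster = FALSE), class = "TrialClassification")
}

#' Lead-lag between population activity and running
#'
#' Lag at the maximum of the normalized cross-correlation between the
#' population-mean trace and the running speed, over +/- `maxLag` seconds.
#' Positive lag means the neuronal activity leads the running-speed
#' increase.
#'
#' @param popTrace population-mean dF/F trace.
#' @param velTrace running speed at the same sampling rate.
#' @param rate sampling rate (Hz).
#' @param maxLag maximum lag (s), less than half the trace length.
#' @return list with `lag` (s, NA and `flag = TRUE` for flat traces),
#'   `lags`, `corrs`.
#' @export
leadLag <- function(popTrace, velTrace, rate, maxLag = 5) {
  n <- length(popTrace)
  if (length(velTrace) != n) stop("traces must share the sampling grid")
  L <- round(maxLag * rate)
  if (L >= n / 2) stop("maxLag must be below half the trace length")
  if (sd(popTrace) == 0 || sd(velTrace) == 0)
    return(list(lag = NA_real_, lags = NULL, corrs = NULL, flag = TRUE))
  lags <- -L:L
  corrs <- vapply(lags, function(l) {
    if (l >= 0) cor(popTrace[1:(n - l)], velTrace[(1 + l):n])
    else cor(popTrace[(1 - l):n], velTrace[1:(n + l)])
  }, numeric(1))
  list(lag = lags[which.max(corrs)] / rate, lags = lags / rate,
       corrs = corrs, flag = FALSE)
}

#' Response onset time
#'
#' First crossing of a fraction of the peak above baseline, on a
#' Gaussian-smoothed trace; used to compare hub-cell and population onset
#' times.
#'
#' @param trace dF/F trace.
#' @param rate sampling rate (Hz).
#' @param frac threshold fraction of the baseline-to-peak range.
#' @param sigmaS smoothing sigma (s).
#' @param baselineFrac leading fraction of samples defining the baseline.
#' @return onset time in seconds from the trace start (NA when flat).
#' @export
onsetTime <- function(trace, rate, frac = 0.2, sigmaS = 0.2,
                      baselineFrac = 0.1) {
  sm <- .gaussSmooth(trace, sigmaS * rate)
  nb <- max(2L, round(baselineFrac * length(sm)))
  b <- mean(sm[seq_len(nb)])
  pk <- max(sm)
  if (pk - b <= 0) return(NA_real_)
  thr <- b + frac * (pk - b)
  ix <- which(sm >= thr)[1L]
  (ix - 1L) / rate
}
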