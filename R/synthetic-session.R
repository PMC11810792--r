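## Synthetic virtual-reality sessions: trial-structured event logs and
## treadmill velocity traces with full ground truth.

## slow AR(1) fluctuation with stationary sd `sdTarget` and time constant tau
.slowFluct <- function(n, dt, sdTarget, tau = 1) {
  rho <- exp(-dt / tau)
  innov <- rnorm(n, 0, sdTarget * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Generate a trial-structured virtual-reality session
#'
#' Simulates a head-fixed visual discrimination session in an infinite
#' virtual corridor: the mouse runs through a neutral corridor and is
#' teleported into grating zones (one aversive, one or more control zones)
#' on average every `meanInterteleport` seconds.  In the aversive zone the
#' mouse has `zoneGrace` seconds to escape before airpuff pulses of
#' `puffDuration` s are delivered every `puffPeriod` s until it leaves.
#' Immobility for `immobilityTimeout` seconds triggers a forced teleport.
#' Treadmill velocity is sampled every `behaviorDt` seconds and may be
#' negative.
#'
#' Learning is injected through `learningCurve`: at each aversive-zone entry
#' the probability of an anticipatory speed-up (and early escape) is
#' `learningCurve(t)` with `t` the session time in seconds.  The speed-up is
#' a smooth velocity increase of `effectSize` running-speed standard
#' deviations, rising over the 1.5 s preceding the scheduled first airpuff —
#' the interval the learning statistic analyses.  With `learningCurve`
#' identically zero the velocity process is identical in aversive and
#' control zones (the exchangeable null).
#'
#' @param config a [SimConfig-class].
#' @param learningCurve function mapping session time (s) to the probability
#'   of an anticipatory speed-up in the aversive zone.
#' @param effectSize speed-up amplitude in units of the running-speed SD.
#' @param lickRate baseline random lick rate (Hz).
#' @param seed RNG seed; defaults to `config@seed`.
#' @return A [SessionLog-class].
#' @examples
#' s <- generateSession(simConfig(seed = 1, nTrialsPerZone = 4L))
#' head(sessionEvents(s))
#' @export
generateSession <- function(config, learningCurve = function(t) 0,
                            effectSize = 3, lickRate = 0.5,
                            seed = config@seed) {
  validObject(config)
  if (!is.function(learningCurve))
    stop("'learningCurve' must be a function of session time")
  set.seed(seed)
  dt <- config@behaviorDt
  zones <- config@zones
  aver <- zones[1L]
  nz <- length(zones)
  trialZones <- sample(rep(zones, config@nTrialsPerZone))
  nTrials <- length(trialZones)

  ## schedule trials sequentially
  entry <- exit <- schedPuff <- numeric(nTrials)
  escaped <- logical(nTrials)
  nPuffs <- integer(nTrials)
  puffTimes <- vector("list", nTrials)
  immobile <- data.frame(start = numeric(0), end = numeric(0))
  tcur <- 5  # initial neutral corridor
  meanDwell <- 4
  for (i in seq_len(nTrials)) {
    if (runif(1) < config@pImmobile) {
      runFor <- runif(1, 2, 6)
      freeze <- tcur + runFor
      tEntry <- freeze + config@immobilityTimeout
      immobile <- rbind(immobile, data.frame(start = freeze, end = tEntry))
    } else {
      neutral <- max(4, rnorm(1, config@meanInterteleport - meanDwell, 3))
      tEntry <- tcur + neutral
    }
    entry[i] <- tEntry
    schedPuff[i] <- tEntry + config@zoneGrace
    esc <- runif(1) < learningCurve(tEntry)
    escaped[i] <- esc && trialZones[i] == aver
    if (escaped[i]) {
      dwell <- runif(1, 2.2, 3.4)           # out before the grace ends
    } else {
      dwell <- config@zoneGrace + runif(1, 0.8, 3.2)
    }
    exit[i] <- tEntry + dwell
    if (trialZones[i] == aver && dwell > config@zoneGrace) {
      pt <- seq(schedPuff[i], exit[i], by = config@puffPeriod)
      pt <- pt[pt < exit[i]]
      puffTimes[[i]] <- pt
      nPuffs[i] <- length(pt)
    }
    tcur <- exit[i]
  }
  duration <- tcur + 8

  ## velocity trace
  n <- ceiling(duration / dt) + 1L
  tv <- (seq_len(n) - 1L) * dt
  v <- config@baselineVelocity +
    .slowFluct(n, dt, config@velocitySd) +
    rnorm(n, 0, 0.3)
  ## anticipatory speed-up: smooth rise over the 1.5 s before the scheduled
  ## first airpuff on speed-up trials
  bumpAmp <- effectSize * config@velocitySd
  for (i in which(escaped)) {
    w0 <- schedPuff[i] - 1.5
    sel <- which(tv >= w0 & tv <= schedPuff[i] + 0.5)
    if (length(sel)) {
      ramp <- pmin(1, (tv[sel] - w0) / 1.5)
      v[sel] <- v[sel] + bumpAmp * 0.5 * (1 - cos(pi * ramp))
    }
  }
  for (j in seq_len(nrow(immobile)))
    v[tv >= immobile$start[j] & tv < immobile$end[j]] <- 0
  pos <- cumsum(v) * dt

  ## events
  ev <- data.frame(time = entry, kind = "teleport_in", zone = trialZones)
  ev <- rbind(ev, data.frame(time = exit, kind = "zone_exit", zone = trialZones))
  pf <- unlist(puffTimes)
  if (length(pf))
    ev <- rbind(ev, data.frame(time = pf, kind = "airpuff_pulse", zone = aver))
  nLick <- rbinom(1L, n, min(1, lickRate * dt))
  if (nLick > 0)
    ev <- rbind(ev, data.frame(time = sort(runif(nLick, 0, duration)),
                               kind = "lick", zone = "NEUTRAL"))
  ev <- ev[order(ev$time, method = "radix"), , drop = FALSE]
  rownames(ev) <- NULL

  trials <- data.frame(entry = entry, exit = exit, zone = trialZones,
                       scheduledPuff = schedPuff, nPuffs = nPuffs,
                       escaped = escaped,
                       class = ifelse(trialZones == aver, "AVER", "CTRL"))
  new("SessionLog", events = ev,
      velocity = data.frame(time = tv, velocity = v, position = pos),
      behaviorDt = dt, duration = duration, trials = trials,
      zoneGrace = config@zoneGrace)
}

#' Per-trial velocity curves in the pre-airpuff window
#'
#' Extracts, for every grating-zone visit, the treadmill velocity in the
#' `preWindow`-second interval ending at the scheduled first airpuff (zone
#' entry plus the grace period; in control zones no airpuff occurs but the
#' schedule defines the same alignment point).  These are the curves the
#' label-shuffle learning statistic compares.
#'
#' @param session a [SessionLog-class].
#' @param preWindow window length in s (default 1.5).
#' @return list with `curves` (trials x samples matrix), `labels` (integer,
#'   1 = control, 2 = aversive), `times` (trial entry times).
#' @export
trialVelocityCurves <- function(session, preWindow = 1.5) {
  tr <- session@trials
  dt <- session@behaviorDt
  nsamp <- round(preWindow / dt)
  v <- session@velocity$velocity
  tv <- session@velocity$time
  keep <- logical(nrow(tr))
  curves <- matrix(NA_real_, nrow(tr), nsamp)
  for (i in seq_len(nrow(tr))) {
    iEnd <- findInterval(tr$scheduledPuff[i] - 1e-9, tv)
    idx <- (iEnd - nsamp + 1L):iEnd
    if (idx[1L] >= 1L && iEnd <= length(v)) {
      curves[i, ] <- v[idx]
      keep[i] <- TRUE
    }
  }
  list(curves = curves[keep, , drop = FALSE],
       labels = ifelse(tr$class[keep] == "AVER", 2L, 1L),
       times = tr$entry[keep])
}

#' Generate abyss-test (immersion) runs
#'
#' Simulates runs in a virtual linear maze ending in a cliff.  Under the
#' `"moculus"` regime (immersive display) the mouse perceives depth and
#' decelerates to a stop -- or recoils with negative velocity -- before the
#' edge; under the `"monitor"` regime it crosses the edge at unchanged
#' speed.  A configurable fraction of runs stalls far before the edge and
#' never reaches it within the timeout, exercising the failed-trial rule.
#'
#' @param config a [SimConfig-class] (velocity scale and sampling step).
#' @param immersion `"moculus"` or `"monitor"`.
#' @param nRuns number of runs.
#' @param edgeCoord abyss edge position (corridor units).
#' @param visibilityCoord position from which the edge is visible.
#' @param recoilFraction fraction of stopping runs that recoil (negative
#'   velocity) at the edge (moculus regime only).
#' @param failFraction fraction of runs that stall before visibility.
#' @param seed RNG seed.
#' @return list with `runs` (list of data.frames `time`, `velocity`,
#'   `position`), `edgeCoord`, `visibilityCoord`, `immersion`.
#' @export
generateAbyssRuns <- function(config, immersion = c("moculus", "monitor"),
                              nRuns = 10L, edgeCoord = 100,
                              visibilityCoord = 70, recoilFraction = 0.3,
                              failFraction = 0, seed = config@seed) {
  immersion <- match.arg(immersion)
  validObject(config)
  set.seed(seed)
  dt <- config@behaviorDt
  v0 <- max(config@baselineVelocity, 4)
  runs <- vector("list", nRuns)
  nFail <- round(failFraction * nRuns)
  for (r in seq_len(nRuns)) {
    tEnd <- 30
    n <- round(tEnd / dt)
    v <- numeric(n); pos <- numeric(n)
    recoil <- immersion == "moculus" && runif(1) < recoilFraction
    stallAt <- visibilityCoord - 30
    p <- 0
    for (i in seq_len(n)) {
      if (r <= nFail) {                     # stall far before visibility
        vi <- if (p < stallAt) v0 else 0
      } else if (immersion == "monitor") {
        vi <- v0 + rnorm(1, 0, 0.2)        # crosses at unchanged speed
      } else {
        decelStart <- visibilityCoord
        if (p < decelStart) {
          vi <- v0 + rnorm(1, 0, 0.2)
        } else {
          vi <- v0 * (edgeCoord - p) / (edgeCoord - decelStart)
          if (vi < 1.5) vi <- if (recoil && i %% 2000 < 700) -2 else 0
        }
      }
      v[i] <- vi
      p <- p + vi * dt
      pos[i] <- p
    }
    runs[[r]] <- data.frame(time = (seq_len(n) - 1L) * dt,
                            velocity = v, position = pos)
  }
  list(runs = runs, edgeCoord = edgeCoord, visibilityCoord = visibilityCoord,
       immersion = immersion)
}
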