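## Ground-truth latent structure and population dF/F transients.

.alphaKernel <- function(t, tau) ifelse(t < 0, 0, (t / tau) * exp(1 - t / tau))

#' Generate per-neuron ground-truth latent amplitudes
#'
#' Draws the latent structure the downstream analyses are tested against:
#' visual-ON, ramp-like (aversive and control), two-component reinforcement
#' and locomotion-coupled amplitudes per neuron, a hub-cell flag (hub ramps
#' exceed non-hub ramps by a stated margin), and soma positions inside the
#' scan volume.
#'
#' @param config a [SimConfig-class].
#' @param hubMargin minimum ratio of the smallest hub ramp amplitude to the
#'   largest non-hub amplitude.
#' @param fieldSize scan volume edge length (micrometers; the high-NA
#'   objective limits the field of view to about 650 um).
#' @param hubClusterRadius if non-NULL, hub somata are placed inside a
#'   sphere of this radius (um) to plant spatial clustering.
#' @param plantedLead lead of the population ramp over the running-speed
#'   increase (s); stored for lead--lag recovery tests.
#' @param seed RNG seed; defaults to `config@seed`.
#' @return list with `neurons` (data.frame of per-neuron amplitudes, hub
#'   flags and soma coordinates), `plantedLead`, `hubMargin`, `fieldSize`.
#' @export
generateGroundTruth <- function(config, hubMargin = 1.6, fieldSize = 650,
                                hubClusterRadius = NULL, plantedLead = 0,
                                seed = config@seed) {
  validObject(config)
  set.seed(seed)
  n <- config@nNeurons
  nHub <- round(config@hubFraction * n)
  hub <- rep(FALSE, n)
  if (nHub > 0) hub[sample.int(n, nHub)] <- TRUE
  rampLow <- runif(n, 0.2, 0.6)
  rampHigh <- runif(n, hubMargin * 0.6, hubMargin * 0.6 + 0.5)
  rampAver <- ifelse(hub, rampHigh, rampLow)
  xyz <- matrix(runif(3L * n, 0, fieldSize), n, 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  if (!is.null(hubClusterRadius) && nHub > 1) {
    ctr <- runif(3, hubClusterRadius, fieldSize - hubClusterRadius)
    for (i in which(hub)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      xyz[i, ] <- ctr + u * runif(1, 0, hubClusterRadius)
    }
  }
  neurons <- data.frame(
    onAmp = runif(n, 0.1, 0.4),
    rampAmpAver = rampAver,
    rampAmpCtrl = rampAver * runif(n, 0.3, 0.9),
    reinfFirstAmp = runif(n, 0.2, 0.8),
    reinfSecondAmp = runif(n, 0, 0.5),
    locomotionGain = runif(n, 0, 0.3),
    hubFlag = hub)
  neurons <- cbind(neurons, xyz)
  stopifnot(all(neurons$rampAmpAver >= 0), all(neurons$onAmp >= 0))
  list(neurons = neurons, plantedLead = plantedLead, hubMargin = hubMargin,
       fieldSize = fieldSize)
}

#' Generate population dF/F transients from a session and ground truth
#'
#' Each neuron's trace is a sum of latent components tied to the session's
#' trial structure: a visual-ON transient at grating-zone entries, a linear
#' ramp over the last `rampDuration` seconds of each zone visit (amplitude
#' `rampAmpAver` or `rampAmpCtrl` by zone class), a two-component
#' reinforcement response at airpuff times (fast exponential decay plus a
#' slower second component), a locomotion-coupled term proportional to the
#' normalized velocity envelope, and additive Gaussian noise.  All component
#' time courses are returned separately so recovery tests can compare
#' against exact ground truth.
#'
#' @param session a [SessionLog-class].
#' @param truth output of [generateGroundTruth()].
#' @param config a [SimConfig-class].
#' @param onTau visual-ON kernel time constant (s).
#' @param reinfTau fast reinforcement decay time constant (s).
#' @param reinfTau2 slow second-component kernel time constant (s).
#' @param seed RNG seed; defaults to `config@seed`.
#' @return list with `dff` (neurons x frames), `components` (named list of
#'   neurons x frames matrices: on, ramp, reinfFirst, reinfSecond,
#'   locomotion, noise), `time` (frame times, s), `rate`.
#' @export
generateTransients <- function(session, truth, config, onTau = 0.3,
                               reinfTau = 0.5, reinfTau2 = 1,
                               seed = config@seed) {
  set.seed(seed + 1L)
  rate <- config@imagingRate
  nf <- floor(session@duration * rate)
  tf <- (seq_len(nf) - 1L) / rate
  tv <- session@velocity$time
  if (max(tf) > max(tv) + session@behaviorDt)
    stop(sprintf(
      "mismatched time bases: imaging at %.4g Hz extends past the %.4g-Hz behavior trace",
      rate, 1 / session@behaviorDt))
  nn <- nrow(truth$neurons)
  tr <- session@trials
  nb <- truth$neurons

  ## trial-locked scalar time courses shared by all neurons
  onTC <- numeric(nf); rampAverTC <- numeric(nf); rampCtrlTC <- numeric(nf)
  for (i in seq_len(nrow(tr))) {
    onTC <- onTC + .alphaKernel(tf - tr$entry[i], onTau) *
      (tf - tr$entry[i] < 8 * onTau)
    riseStart <- max(tr$entry[i], tr$exit[i] - config@rampDuration)
    inZone <- tf >= riseStart & tf <= tr$exit[i]
    ramp <- numeric(nf)
    ramp[inZone] <- (tf[inZone] - riseStart) / (tr$exit[i] - riseStart)
    if (tr$class[i] == "AVER") rampAverTC <- rampAverTC + ramp
    else rampCtrlTC <- rampCtrlTC + ramp
  }
  ev <- session@events
  puffs <- ev$time[ev$kind == "airpuff_pulse"]
  r1TC <- numeric(nf); r2TC <- numeric(nf)
  for (p in puffs) {
    d <- tf - p
    r1TC <- r1TC + ifelse(d >= 0 & d < 6 * reinfTau, exp(-d / reinfTau), 0)
    r2TC <- r2TC + .alphaKernel(d, reinfTau2) * (d < 8 * reinfTau2)
  }
  vImg <- approx(tv, session@velocity$velocity, xout = tf, rule = 2)$y
  env <- pmax(vImg, 0)
  if (max(env) > 0) env <- env / max(env)

  comp <- function(amp, tc) outer(amp, tc)
  on <- comp(nb$onAmp, onTC)
  rampM <- comp(nb$rampAmpAver, rampAverTC) + comp(nb$rampAmpCtrl, rampCtrlTC)
  r1 <- comp(nb$reinfFirstAmp, r1TC)
  r2 <- comp(nb$reinfSecondAmp, r2TC)
  loco <- comp(nb$locomotionGain, env)
  noise <- matrix(rnorm(nn * nf, 0, config@noiseSd), nn, nf)
  dffM <- on + rampM + r1 + r2 + loco + noise
  list(dff = dffM,
       components = list(on = on, ramp = rampM, reinfFirst = r1,
                         reinfSecond = r2, locomotion = loco, noise = noise),
       time = tf, rate = rate)
}
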