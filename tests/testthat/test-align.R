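test_that("alignment windows have round(preWindow * rate) samples, right-closed", {
  cfg <- testConfig(seed = 61)
  s <- generateSession(cfg)
  gt <- generateGroundTruth(cfg)
  tr <- generateTransients(s, gt, cfg)
  al <- alignToZoneEnd(tr$dff, s, preWindow = 5, rate = 14.31)
  expect_equal(dim(responseTensor(al))[2], 72)  # round(5 * 14.31)
  expect_equal(max(timeAxis(al)), 0)
  ## last sample is the frame at or before the zone exit
  info <- al@trialInfo
  tf <- (seq_len(ncol(tr$dff)) - 1) / 14.31
  for (k in seq_len(nrow(info))) {
    iEnd <- findInterval(info$exit[k] + 1e-9, tf)
    expect_equal(responseTensor(al)[, 72, k], tr$dff[, iEnd])
  }
})

test_that("trials shorter than the window are dropped with a reported count", {
  dffM <- matrix(rnorm(2 * 40), 2, 40)      # 40 frames at 10 Hz = 4 s
  s <- generateSession(testConfig(seed = 62, nTrialsPerZone = 3L))
  s@trials$exit[1] <- 2                     # trial ending at 2 s < 5-s window
  al <- alignToZoneEnd(dffM, s, preWindow = 3, rate = 10)
  expect_gte(attr(al, "dropped"), 1)
})

test_that("capping at the scheduled airpuff ends aversive windows before reinforcement", {
  cfg <- testConfig(seed = 63)
  s <- generateSession(cfg)
  gt <- generateGroundTruth(cfg)
  tr <- generateTransients(s, gt, cfg)
  al <- alignToZoneEnd(tr$dff, s, preWindow = 4, rate = cfg@imagingRate,
                       capAtPuff = TRUE)
  info <- al@trialInfo
  aver <- info$class == "AVER"
  ## reinforcement components are zero inside capped aversive windows
  tf <- tr$time
  nsamp <- dim(responseTensor(al))[2]
  for (k in which(aver)) {
    endT <- min(info$exit[k], info$scheduledPuff[k])
    iEnd <- findInterval(endT + 1e-9, tf)
    idx <- (iEnd - nsamp + 1):iEnd
    expect_equal(max(abs(tr$components$reinfFirst[, idx[idx > 0]])), 0)
  }
})

test_that("ramp amplitude equals the closed-form window mean and is linear", {
  rate <- 200
  nt <- 5 * rate
  tax <- (-(nt - 1):0) / rate
  tracev <- tax + 5                          # trace(t) = t + 5 on [-5, 0]
  resp <- array(0, c(2, nt, 3))
  for (k in 1:3) { resp[1, , k] <- tracev; resp[2, , k] <- 2 * tracev }
  al <- makeAligned(resp, c("AVER", "AVER", "CTRL"), rate = rate)
  ra <- rampAmplitude(al, window = c(-1, -0.4))
  expect_equal(unname(ra$perNeuron[1]), 4.3, tolerance = 1e-2)
  ## linearity: amplitude(a x + b y) = a amplitude(x) + b amplitude(y)
  expect_equal(ra$perNeuron[2], 2 * ra$perNeuron[1])
  resp2 <- resp; resp2[1, , ] <- 3 * resp[1, , ] + 0.5 * resp[2, , ]
  al2 <- makeAligned(resp2, c("AVER", "AVER", "CTRL"), rate = rate)
  ra2 <- rampAmplitude(al2)
  expect_equal(ra2$perNeuron[1],
               3 * ra$perNeuron[1] + 0.5 * ra$perNeuron[2])
  ## zero trace -> zero amplitude; integral mode scales by window length
  expect_equal(unname(rampAmplitude(makeAligned(array(0, c(1, nt, 2)),
                                                c("AVER", "CTRL"),
                                                rate = rate))$perNeuron), 0)
  ri <- rampAmplitude(al, mode = "integral")
  expect_equal(ri$perNeuron, ra$perNeuron * 0.6)
})

test_that("the two conventional windows rank noiseless planted ramps identically", {
  rate <- 14.31
  nt <- 72
  tax <- (-(nt - 1):0) / rate
  amps <- runif(30, 0.1, 2)
  resp <- array(0, c(30, nt, 4))
  shape <- pmax(0, (tax + 3) / 3)
  for (k in 1:4) resp[, , k] <- outer(amps, shape)
  al <- makeAligned(resp, c("AVER", "AVER", "CTRL", "CTRL"), rate = rate)
  r1 <- rampAmplitude(al, c(-1, -0.4))$perNeuron
  r2 <- rampAmplitude(al, c(-1, -0.3))$perNeuron
  expect_equal(cor(rank(r1), rank(r2)), 1)
  expect_error(rampAmplitude(al, c(-0.401, -0.400)), "empty window")
})
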