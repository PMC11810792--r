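## planted separable populations: a subset of neurons ramps only in
## aversive trials over the whole pre-window
plantSeparable <- function(nNeurons = 20, nAver = 5, nTrials = 40,
                           amp = 0.6, noise = 0.2, seed = 1, rate = 14.31,
                           nt = 72) {
  set.seed(seed)
  labels <- rep(c("AVER", "CTRL"), length.out = nTrials)
  resp <- array(rnorm(nNeurons * nt * nTrials, 0, noise),
                c(nNeurons, nt, nTrials))
  tax <- (-(nt - 1):0) / rate
  shape <- (tax - min(tax)) / diff(range(tax))   # rises over the window
  for (i in seq_len(nAver))
    for (k in which(labels == "AVER"))
      resp[i, , k] <- resp[i, , k] + amp * shape
  list(aligned = makeAligned(resp, labels, rate = rate), labels = labels)
}

test_that("the decoder separates planted separable populations with high reliability", {
  ps <- plantSeparable(noise = 0.2, amp = 0.6, seed = 2)
  dec <- buildDecoder(ps$aligned, seed = 1)
  expect_gte(dec$reliability, 0.95)
  expect_true(all(dec$members <= 5))
  expect_true(dec$k >= 3 && dec$k <= 7)
})

test_that("decoder reliability is at chance under permuted labels", {
  rel <- vapply(1:20, function(seed) {
    ps <- plantSeparable(seed = seed)
    set.seed(seed + 100)
    perm <- sample(ps$labels)
    al <- makeAligned(responseTensor(ps$aligned), perm)
    buildDecoder(al, seed = seed)$reliability
  }, numeric(1))
  expect_lt(abs(mean(rel) - 0.5), 0.1)
})

test_that("k = 3 and k = 7 label noiseless separable trials identically", {
  ps <- plantSeparable(nNeurons = 10, nAver = 7, noise = 0, amp = 1,
                       seed = 3)
  d3 <- buildDecoder(ps$aligned, k = 3, seed = 1)
  d7 <- buildDecoder(ps$aligned, k = 7, seed = 1)
  expect_identical(d3$predicted, d7$predicted)
  expect_equal(d3$reliability, 1)
  expect_error(buildDecoder(ps$aligned, k = 8), "3..7")
  expect_error(buildDecoder(ps$aligned, k = 2), "3..7")
})

test_that("degenerate train/test splits are rejected", {
  ps <- plantSeparable(seed = 4)
  expect_error(buildDecoder(ps$aligned,
                            trainTrials = which(ps$labels == "AVER")),
               "degenerate")
  expect_error(buildDecoder(ps$aligned, trainTrials = 1:40), "degenerate")
})

test_that("trial clustering splits separated ramp scores and is scale invariant", {
  scores <- c(rep(0.1, 5), rep(1.0, 5))
  vel <- scores + rnorm(10, 0, 0.01)
  tc <- clusterTrials(scores, vel, seed = 1)
  expect_equal(tc$labels, rep(c("low_ramp", "high_ramp"), each = 5))
  tc2 <- clusterTrials(scores * 40, vel, seed = 1)
  expect_identical(tc$labels, tc2$labels)
  ## identical scores: single-cluster flag
  expect_true(clusterTrials(rep(1, 8), rnorm(8))$singleCluster)
  expect_error(clusterTrials(1:5, 1:5), "6 trials")
})

test_that("velocity built as 0.9 ramp + noise correlates in the published range", {
  set.seed(12)
  rs <- vapply(1:30, function(i) {
    ramp <- runif(30, 0, 1)
    vel <- 0.9 * ramp + rnorm(30, 0, 0.1)
    clusterTrials(ramp, vel, seed = i)$r
  }, numeric(1))
  expect_true(all(rs > 0.85 & rs < 0.995))
})

test_that("lead-lag recovers a planted lead within one sample", {
  rate <- 14.31
  n <- 600
  base <- calciumvr:::.gaussSmooth(rnorm(n), 6)
  k <- round(2.45 * rate)                      # planted 2.45-s lead
  pop <- base
  vel <- c(rep(0, k), base[1:(n - k)])         # velocity trails the ramp
  ll <- leadLag(pop, vel, rate, maxLag = 5)
  expect_lt(abs(ll$lag - 2.45), 1 / rate + 1e-9)
  ## identical traces: zero lag; flat trace flagged
  expect_equal(leadLag(pop, pop, rate, maxLag = 3)$lag, 0)
  expect_true(leadLag(rep(1, n), vel, rate)$flag)
  ## running-leads structure gives a negative lag
  velLead <- c(base[(k + 1):n], rep(0, k))
  expect_lt(leadLag(pop, velLead, rate, maxLag = 5)$lag, 0)
})

test_that("hub ramps starting earlier give onset differences of at least 1 s", {
  rate <- 14.31
  tax <- seq(-8, 0, by = 1 / rate)
  ## hub ramp is the population ramp shifted 1.2 s earlier
  mk <- function(onset) pmin(1, pmax(0, (tax - onset) / 3))
  hub <- mk(-4.2); popn <- mk(-3)
  oh <- onsetTime(hub, rate)
  op <- onsetTime(popn, rate)
  expect_gte(op - oh, 1)
})
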