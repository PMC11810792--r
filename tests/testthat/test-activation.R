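## planted aligned tensors: baseline noise plus optional response-window
## offsets per neuron
plantResponses <- function(n, nTrials, amp, noise = 0.1, rate = 14.31,
                           nt = 72, seed = 1) {
  set.seed(seed)
  resp <- array(rnorm(n * nt * nTrials, 0, noise), c(n, nt, nTrials))
  tax <- (-(nt - 1):0) / rate
  ri <- which(tax >= -1 & tax <= -0.4)
  for (i in seq_len(n)) resp[i, ri, ] <- resp[i, ri, ] + amp[i]
  makeAligned(resp, rep(c("AVER", "CTRL"), length.out = nTrials),
              rate = rate)
}

test_that("paired t-test activation is calibrated to the nominal type-I level", {
  fr <- vapply(1:200, function(seed) {
    al <- plantResponses(20, 8, rep(0, 20), seed = seed)
    activationRatio(al, baselineWindow = c(-5, -4), method = "paired_t")$fraction
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.05), 0.02)
})

test_that("planted responders at high SNR are detected at the planted fraction", {
  amp <- c(rep(0.5, 80), rep(0, 20))    # 80% responders, SNR >= 5
  fr <- vapply(1:10, function(seed) {
    al <- plantResponses(100, 10, amp, noise = 0.1, seed = seed)
    activationRatio(al, baselineWindow = c(-5, -4), method = "paired_t")$fraction
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.80), 0.05)
})

test_that("the 2-sem threshold flags a deterministic toy responder and is monotone in amplitude", {
  nt <- 72
  resp <- array(0, c(2, nt, 3))
  tax <- (-(nt - 1):0) / 14.31
  ri <- tax >= -1 & tax <= -0.4
  resp[1, ri, ] <- 1                      # baseline 0,0,0 -> response 1,1,1
  al <- makeAligned(resp, c("AVER", "CTRL", "AVER"))
  ar <- activationRatio(al, baselineWindow = c(-5, -4),
                        method = "threshold_2sem")
  expect_true(ar$active[1])
  expect_false(ar$active[2])
  ## monotonicity across planted amplitude
  fracs <- vapply(c(0, 0.1, 0.3, 0.6), function(a) {
    al <- plantResponses(40, 8, rep(a, 40), noise = 0.1, seed = 5)
    activationRatio(al, baselineWindow = c(-5, -4),
                    method = "threshold_2sem")$fraction
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  ## single trial is rejected for the paired test
  one <- makeAligned(array(rnorm(2 * nt), c(2, nt, 1)), "AVER")
  expect_error(activationRatio(one, method = "paired_t"), "2 trials")
})

test_that("zone preference recovers planted population fractions", {
  set.seed(77)
  n <- 100; nTrials <- 20
  nt <- 72; rate <- 14.31
  tax <- (-(nt - 1):0) / rate
  ri <- which(tax >= -1 & tax <= -0.4)
  labels <- rep(c("AVER", "CTRL"), length.out = nTrials)
  resp <- array(rnorm(n * nt * nTrials, 0, 0.1), c(n, nt, nTrials))
  kind <- rep(c("A", "C", "N"), times = c(44, 14, 42))
  for (i in seq_len(n)) {
    if (kind[i] == "A")
      resp[i, ri, labels == "AVER"] <- resp[i, ri, labels == "AVER"] + 0.5
    if (kind[i] == "C")
      resp[i, ri, labels == "CTRL"] <- resp[i, ri, labels == "CTRL"] + 0.5
  }
  al <- makeAligned(resp, labels, rate = rate)
  zp <- classifyZonePreference(al)
  expect_lt(abs(zp$fractions[["AVER"]] - 0.44), 0.05)
  expect_lt(abs(zp$fractions[["CTRL"]] - 0.14), 0.05)
  ## identical planted responses stay near the test level
  respNull <- array(rnorm(50 * nt * nTrials, 0, 0.1), c(50, nt, nTrials))
  zpNull <- classifyZonePreference(makeAligned(respNull, labels, rate = rate))
  expect_lt(zpNull$fractions[["AVER"]] + zpNull$fractions[["CTRL"]], 0.15)
})

test_that("a single strongly aversive-preferring neuron is labeled AVER-coding", {
  nt <- 72; rate <- 14.31
  tax <- (-(nt - 1):0) / rate
  ri <- which(tax >= -1 & tax <= -0.4)
  labels <- rep(c("AVER", "CTRL"), each = 10)
  set.seed(3)
  resp <- array(rnorm(1 * nt * 20, 0, 0.05), c(1, nt, 20))
  resp[1, ri, labels == "AVER"] <- resp[1, ri, labels == "AVER"] + 1
  zp <- classifyZonePreference(makeAligned(resp, labels, rate = rate))
  expect_equal(zp$labels, "AVER-coding")
})
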