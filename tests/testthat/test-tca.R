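plantTensor <- function(I = 30, J = 40, K = 12, rank = 3, seed = 1,
                        noise = 0) {
  set.seed(seed)
  A <- matrix(runif(I * rank), I)
  tt <- seq_len(J) / J
  B <- cbind(tt,                                  # ramp
             exp(-((tt - 0.5)^2) / 0.02),         # motion-like bump
             exp(-((tt - 0.12)^2) / 0.005))[, seq_len(rank), drop = FALSE]
  C <- matrix(runif(K * rank, 0.2, 1), K)
  X <- array(0, c(I, J, K))
  for (r in seq_len(rank))
    X <- X + outer(outer(A[, r], B[, r]), C[, r])
  if (noise > 0) X <- pmax(X + array(rnorm(length(X), 0, noise * sd(X)),
                                     dim(X)), 0)
  list(X = X, A = A, B = B, C = C)
}

test_that("tensor building filters, crops, clips and attaches motion integrals", {
  cfg <- testConfig(seed = 71)
  s <- generateSession(cfg)
  gt <- generateGroundTruth(cfg)
  tr <- generateTransients(s, gt, cfg)
  al <- alignToZoneEnd(tr$dff, s, preWindow = 6, rate = cfg@imagingRate)
  tt <- buildTensor(al, crop = 5, sigma = 0)
  expect_equal(dim(tt$data)[2], 72)            # 5 s at 14.31 Hz
  expect_gte(min(tt$data), 0)
  ## sigma -> 0: tensor equals the cropped clipped input
  nt <- dim(responseTensor(al))[2]
  expect_equal(tt$data,
               pmax(responseTensor(al)[, (nt - 71):nt, , drop = FALSE], 0))
  expect_length(tt$motion, length(zoneLabels(al)))
  ## NaN rejection names the trial
  bad <- responseTensor(al); bad[1, 1, 2] <- NaN
  alBad <- makeAligned(bad, zoneLabels(al), rate = cfg@imagingRate)
  expect_error(buildTensor(alBad, crop = 5), "trial\\(s\\): 2")
})

test_that("the truncated Gaussian kernel is normalized and matches dnorm shape", {
  k <- calciumvr:::.gaussKernel(2)
  expect_equal(sum(k), 1)
  r <- (length(k) - 1) / 2
  expect_equal(k, dnorm(-r:r, 0, 2) / sum(dnorm(-r:r, 0, 2)))
  ## impulse response reproduces the kernel
  x <- numeric(31); x[16] <- 1
  sm <- calciumvr:::.gaussSmooth(x, 2)
  expect_equal(sm[(16 - r):(16 + r)], k, tolerance = 1e-12)
})

test_that("a nonnegative rank-1 tensor is recovered essentially exactly", {
  set.seed(19)
  u <- runif(12); v <- runif(15); w <- runif(8)
  X <- outer(outer(u, v), w)
  fit <- cpDecomposeNonneg(X, rank = 1, nRestarts = 2, seed = 4)
  expect_lt(fit@error, 1e-8)
  cu <- abs(sum(factorMatrix(fit, "neuron") * u) /
              sqrt(sum(u^2)))   # neuron factor is unit-norm
  expect_gt(cu, 0.999)
})

test_that("planted rank-3 latents are recovered with congruence above 0.9 under noise", {
  pt <- plantTensor(I = 40, J = 50, K = 16, rank = 3, seed = 20,
                    noise = 0.05)
  fit <- cpDecomposeNonneg(pt$X, rank = 3, nRestarts = 3, seed = 5)
  sc <- matchFactors(fit, pt)
  expect_true(all(sc > 0.9))
})

test_that("the decomposition is deterministic given a seed and monotone in objective", {
  pt <- plantTensor(seed = 21, noise = 0.1)
  f1 <- cpDecomposeNonneg(pt$X, rank = 2, nRestarts = 2, seed = 6)
  f2 <- cpDecomposeNonneg(pt$X, rank = 2, nRestarts = 2, seed = 6)
  expect_identical(factorMatrix(f1, "trial"), factorMatrix(f2, "trial"))
  expect_true(all(diff(f1@objective) <= 1e-8))
  ## zero tensor: zero factors with a flag
  f0 <- cpDecomposeNonneg(array(0, c(3, 4, 5)), rank = 2)
  expect_true(attr(f0, "zeroTensor"))
  expect_equal(max(factorMatrix(f0, "neuron")), 0)
})

test_that("reconstruction error at the planted rank beats rank minus one", {
  pt <- plantTensor(I = 20, J = 30, K = 10, rank = 3, seed = 22,
                    noise = 0.02)
  e3 <- cpDecomposeNonneg(pt$X, rank = 3, nRestarts = 2, seed = 7)@error
  e2 <- cpDecomposeNonneg(pt$X, rank = 2, nRestarts = 2, seed = 7)@error
  expect_lt(e3, e2)
})

test_that("factor interpretation tags kinetics and detects zone preference", {
  set.seed(23)
  K <- 20
  labels <- rep(c("AVER", "CTRL"), each = K / 2)
  motion <- runif(K, 0, 10)
  tf <- cbind(motion * 1.0,                          # exactly motion-coupled
              ifelse(labels == "AVER", 5, 1) * runif(K, 0.8, 1.2))
  tm <- cbind(seq(0, 1, length.out = 30),            # strictly increasing
              exp(-((seq(0, 1, length.out = 30) - 0.1)^2) / 0.01))
  nf <- matrix(runif(10 * 2), 10)
  fit <- new("CPFactors", neuron = nf, time = tm, trial = tf,
             rank = 2L, error = 0.1, objective = 0.1, converged = TRUE)
  intp <- interpretFactors(fit, motion, labels)
  expect_equal(intp$motionR[1], 1)
  expect_equal(intp$kinetics, c("ramp", "ON"))
  expect_lt(intp$pT[2], 0.05)
  expect_lt(intp$pMW[2], 0.05)
})

test_that("cross-split rank selection does not overfit a planted rank", {
  pt <- plantTensor(I = 15, J = 24, K = 12, rank = 2, seed = 24,
                    noise = 0.05)
  rs <- selectRank(pt$X, ranks = 1:4, seed = 2, nRestarts = 1)
  expect_gte(rs$rank, 2)
  expect_lte(rs$rank, 3)
})
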