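mkMovie <- function(frames, fill = 0, rate = 14.31) {
  new("ChessboardMovie", frames = frames, gridShape = c(1L, 1L),
      frameRate = rate, centers = matrix(0, 1, 3), fillValue = fill)
}

test_that("zero-motion movie yields all-zero shifts and an unchanged movie", {
  ref <- smoothImage(24, 24, seed = 1)
  arr <- array(0, c(5, 24, 24))
  for (f in 1:5) arr[f, , ] <- ref
  mv <- mkMovie(list(`1_1` = arr))
  rg <- registerSubfields(mv, upsample = 10)
  expect_equal(max(abs(rg$shifts[["1_1"]])), 0)
  expect_equal(rg$corrected@frames[["1_1"]], arr)
})

test_that("planted integer shifts are recovered exactly and match the exhaustive oracle", {
  ref <- smoothImage(24, 24, seed = 2)
  shifted <- calciumvr:::.shiftMatrix(ref, 2, 3, fill = 0)
  est <- calciumvr:::.estimateShift(shifted, ref, upsample = 1)
  expect_equal(est$shift, c(2, 3))
  ## oracle: exhaustive integer-shift search maximizing correlation
  best <- c(NA, NA); bestC <- -Inf
  for (dy in -5:5) for (dx in -5:5) {
    cand <- calciumvr:::.shiftMatrix(ref, dy, dx, fill = 0)
    cc <- cor(as.numeric(cand), as.numeric(shifted))
    if (cc > bestC) { bestC <- cc; best <- c(dy, dx) }
  }
  expect_equal(best, c(2, 3))
  expect_equal(est$shift, best)
})

test_that("half-pixel shifts are recovered within 0.1 px and agree with dense correlation", {
  ref <- smoothImage(24, 24, seed = 3)
  img <- fourierShift(ref, 0.5, 0)
  est <- calciumvr:::.estimateShift(img, ref, upsample = 10)
  expect_lt(abs(est$shift[1] - 0.5), 0.1)
  expect_lt(abs(est$shift[2] - 0), 0.1)
  ## oracle: dense evaluation of the correlation on a 0.05-px grid
  grid <- seq(0, 1, by = 0.05)
  cc <- vapply(grid, function(u)
    cor(as.numeric(fourierShift(ref, u, 0)), as.numeric(img)), numeric(1))
  expect_lt(abs(grid[which.max(cc)] - 0.5), 0.05 + 1e-9)
  expect_lt(abs(est$shift[1] - grid[which.max(cc)]), 0.1)
})

test_that("integer-shift estimates are equivariant under additional shifts", {
  ref <- smoothImage(24, 24, seed = 4)
  base <- calciumvr:::.shiftMatrix(ref, 1, -1, fill = 0)
  more <- calciumvr:::.shiftMatrix(ref, 3, 1, fill = 0)  # (1,-1) + (2,2)
  e1 <- calciumvr:::.estimateShift(base, ref, upsample = 1)$shift
  e2 <- calciumvr:::.estimateShift(more, ref, upsample = 1)$shift
  expect_equal(e2 - e1, c(2, 2))
})

test_that("flat subfields yield shift (0,0) with a warning flag, not an error", {
  arr <- array(1, c(3, 12, 12))
  mv <- mkMovie(list(`1_1` = arr))
  rg <- registerSubfields(mv)
  expect_true(rg$flatFlags[["1_1"]])
  expect_equal(max(abs(rg$shifts[["1_1"]])), 0)
})

test_that("registration undoes planted motion in a rendered movie", {
  cfg <- testConfig(seed = 12, noiseSd = 0.02)
  s <- generateSession(cfg)
  gt <- generateGroundTruth(cfg)
  tr <- generateTransients(s, gt, cfg)
  nf <- ncol(tr$dff)
  motion <- matrix(0L, nf, 2)
  moved <- seq(20, nf, by = 7)
  motion[moved, 1] <- 2L; motion[moved, 2] <- 3L
  mv <- generateChessboardMovie(gt, tr, cfg, motion = motion)
  rg <- registerSubfields(mv$movie, upsample = 1,
                          refFrames = 10)  # reference: first measurement unit
  sh <- rg$shifts[[1]]
  expect_equal(unname(sh[moved, 1]), rep(2, length(moved)))
  expect_equal(unname(sh[moved, 2]), rep(3, length(moved)))
  expect_equal(max(abs(sh[-moved, ])), 0)
})
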