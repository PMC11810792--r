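## toy one-subfield fixtures with hand-enumerable geometry

toyRoiSet <- function(somaPix, npPix, h = 10L, w = 10L, extra = NULL) {
  rois <- list(list(somaPix = somaPix,
                    somaW = rep(1 / nrow(somaPix), nrow(somaPix)),
                    npPix = npPix, npW = rep(1 / nrow(npPix), nrow(npPix)),
                    homeSubfield = "1_1", somaXYZ = c(0, 0, 0)))
  if (!is.null(extra)) rois <- c(rois, list(extra))
  new("RoiSet", rois = rois, subfieldSize = c(h, w), gridShape = c(1L, 2L))
}

toyMovie <- function(nf = 4L, h = 10L, w = 10L, value = 5) {
  arr <- array(value, c(nf, h, w))
  new("ChessboardMovie", frames = list(`1_1` = arr),
      gridShape = c(1L, 2L), frameRate = 10, centers = matrix(0, 1, 3),
      fillValue = 0)
}

test_that("clean movies drop zero pixels and keep weights up to normalization", {
  soma <- as.matrix(expand.grid(r = 2:5, c = 2:6))
  rs <- toyRoiSet(soma, npPix = cbind(8:9, 8:9))
  mv <- toyMovie()
  cl <- cleanRoiPixels(mv, rs)
  expect_equal(cl[[1]]$dropped, 0)
  expect_equal(cl[[1]]$weights, rep(1 / nrow(soma), nrow(soma)))
  expect_true(cl[[1]]$valid)
  ## idempotence: cleaning the already-clean extraction changes nothing
  cl2 <- cleanRoiPixels(mv, rs)
  expect_identical(cl, cl2)
})

test_that("a 2-px shift invalidates exactly the geometrically enumerated pixels", {
  ## 20 soma pixels in rows 1..4; a +2 row shift fills rows 1..2 with zero,
  ## so the 5 pixels sitting in rows 1..2 are invalidated
  soma <- rbind(as.matrix(expand.grid(r = 1:2, c = 3:4)),   # 4 px in rows 1-2
                cbind(r = 1, c = 7),                        # 1 px in row 1
                as.matrix(expand.grid(r = 3:5, c = 2:6)))   # 15 px below
  expect_equal(nrow(soma), 20)
  expect_equal(sum(soma[, 1] <= 2), 5)
  mv <- toyMovie(nf = 6)
  mv@frames[["1_1"]][4, , ] <-
    calciumvr:::.shiftMatrix(mv@frames[["1_1"]][4, , ], 2, 0, fill = 0)
  rs <- toyRoiSet(soma, npPix = cbind(9, 9))
  cl <- cleanRoiPixels(mv, rs)
  expect_equal(cl[[1]]$dropped, 5)
  expect_equal(nrow(cl[[1]]$keptPix), 15)
  expect_equal(sum(cl[[1]]$weights), 1)
})

test_that("an ROI with every pixel invalidated is flagged invalid, not an error", {
  mv <- toyMovie(nf = 3, value = 0)  # all-zero movie: everything invalid
  rs <- toyRoiSet(cbind(2:4, 2:4), npPix = cbind(9, 9))
  cl <- cleanRoiPixels(mv, rs)
  expect_false(cl[[1]]$valid)
  expect_equal(cl[[1]]$dropped, 3)
})

test_that("neuropil pixels outside the chessboard frame are removed by exact count", {
  ## 40-px annulus with 12 px spilling past the right border (col > 10)
  np <- rbind(as.matrix(expand.grid(r = 1:7, c = 4:7)),   # 28 inside
              as.matrix(expand.grid(r = 1:6, c = 11:12))) # 12 outside
  expect_equal(nrow(np), 40)
  rs <- toyRoiSet(cbind(9, 1), np)
  out <- cleanNeuropilPixels(rs)
  expect_equal(nrow(out@rois[[1]]$npPix), 28)
  expect_equal(out@rois[[1]]$npDropped, 12)
  expect_equal(out@rois[[1]]$npW, rep(1 / 28, 28))
})

test_that("neuropil pixels overlapping another ROI soma are removed", {
  otherSoma <- as.matrix(expand.grid(r = 6:7, c = 6:7))
  extra <- list(somaPix = otherSoma, somaW = rep(0.25, 4),
                npPix = cbind(1, 1), npW = 1, homeSubfield = "1_1",
                somaXYZ = c(0, 0, 0))
  np <- rbind(cbind(6, 6), cbind(6, 7), cbind(7, 6),  # 3 px overlap
              as.matrix(expand.grid(r = 1:3, c = 1:3)))
  rs <- toyRoiSet(cbind(9, 9), np, extra = extra)
  out <- cleanNeuropilPixels(rs)
  expect_equal(out@rois[[1]]$npDropped, 3)
  expect_equal(nrow(out@rois[[1]]$npPix), 9)
})

test_that("an annulus fully inside its subfield with no overlap is unchanged and cleaning is idempotent", {
  np <- as.matrix(expand.grid(r = 1:4, c = 1:4))
  rs <- toyRoiSet(cbind(9, 9), np)
  out <- cleanNeuropilPixels(rs)
  expect_equal(out@rois[[1]]$npPix, np)
  out2 <- cleanNeuropilPixels(out)
  expect_equal(out2@rois[[1]]$npPix, out@rois[[1]]$npPix)
  ## empty neuropil flag
  rsEmpty <- toyRoiSet(cbind(9, 9), cbind(11, 11))
  expect_true(cleanNeuropilPixels(rsEmpty)@rois[[1]]$npEmpty)
})
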