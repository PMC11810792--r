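test_that("the forward model matches hand evaluation and fixes the center", {
  ident <- distortionModel(c(0, 0, 0))
  pts <- cbind(runif(20, -1, 1), runif(20, -1, 1))
  expect_equal(applyDistortion(pts, ident), unname(pts))
  m <- distortionModel(c(0.1, 0, 0))
  expect_equal(applyDistortion(c(0.5, 0), m)[1, ], c(0.5125, 0))
  expect_equal(applyDistortion(c(0, 0), m)[1, ], c(0, 0))
})

test_that("the forward model is rotationally equivariant", {
  m <- distortionModel(c(0.08, -0.01, 0.002))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts <- cbind(runif(50, -0.6, 0.6), runif(50, -0.6, 0.6))
  expect_equal(applyDistortion(pts %*% t(R), m),
               applyDistortion(pts, m) %*% t(R), tolerance = 1e-12)
})

test_that("inversion round-trips the forward model below tolerance", {
  m <- distortionModel(c(0.08, -0.01, 0.001))
  g <- as.matrix(expand.grid(x = seq(-0.9, 0.9, length.out = 32),
                             y = seq(-0.9, 0.9, length.out = 32)))
  d <- applyDistortion(g, m)
  u <- invertDistortion(d, m, tol = 1e-9)
  expect_lt(max(abs(u - g)), 1e-6)
  ident <- distortionModel(c(0, 0, 0))
  expect_equal(invertDistortion(g, ident), unname(g))
  expect_equal(invertDistortion(c(0, 0), m)[1, ], c(0, 0))
})

test_that("inversion residual stays below tolerance over random monotone models", {
  set.seed(25)
  for (i in 1:25) {
    k <- c(runif(1, -0.1, 0.15), runif(1, -0.02, 0.02),
           runif(1, -0.005, 0.005))
    m <- distortionModel(k)
    if (!calciumvr:::.isMonotone(m, 1.0)) next
    pts <- cbind(runif(100, -0.7, 0.7), runif(100, -0.7, 0.7))
    d <- applyDistortion(pts, m)
    u <- invertDistortion(d, m, tol = 1e-9)
    expect_lt(max(abs(applyDistortion(u, m) - d)), 1e-8)
  }
})

test_that("a strongly nonmonotone model is rejected before inversion", {
  m <- distortionModel(c(-1.2, 0, 0))   # derivative < 0 inside r <= 1
  expect_error(applyDistortion(c(0.9, 0), m), "monotone")
})

test_that("coefficient estimation recovers planted coefficients from grids", {
  m <- distortionModel(c(0.1, 0.02, -0.005))
  g <- as.matrix(expand.grid(x = seq(-0.7, 0.7, length.out = 10),
                             y = seq(-0.7, 0.7, length.out = 10)))
  d <- applyDistortion(g, m)
  est <- estimateDistortion(g, d)
  expect_lt(max(abs(distortionCoefs(est$model) - c(0.1, 0.02, -0.005))),
            1e-4)
  expect_lt(est$rms, 1e-8)
  ## identity pairs give zero coefficients
  est0 <- estimateDistortion(g, g)
  expect_lt(max(abs(distortionCoefs(est0$model))), 1e-8)
  ## 1% coordinate noise: K1 within 10%
  set.seed(26)
  dn <- d + matrix(rnorm(length(d), 0, 0.01 * sd(d)), nrow(d))
  estN <- estimateDistortion(g, dn)
  expect_lt(abs(distortionCoefs(estN$model)[1] - 0.1), 0.01)
  ## degenerate geometry rejected
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  circ <- 0.5 * cbind(cos(th), sin(th))
  expect_error(estimateDistortion(circ, circ), "single radius")
})

test_that("the sign rule classifies barrel, pincushion and mustache", {
  expect_equal(classifyDistortion(c(0.1, 0.02, 0)), "pincushion")
  expect_equal(classifyDistortion(c(-0.1, -0.02, 0)), "barrel")
  expect_equal(classifyDistortion(c(0.1, -0.02, 0)), "mustache")
  expect_equal(classifyDistortion(c(0, 0, 0)), "none")
  ## all mixed-sign patterns with three nonzero coefficients are mustache
  for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
    k <- c(s1 * 0.1, s2 * 0.01, s3 * 0.001)
    expected <- if (all(sign(k) > 0)) "pincushion"
    else if (all(sign(k) < 0)) "barrel" else "mustache"
    expect_equal(classifyDistortion(k), expected)
  }
})
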