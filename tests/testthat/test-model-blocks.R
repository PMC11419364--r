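# The block library: activations, SPPF window arithmetic and pooling
# equivalence, squeeze-excitation, inverted residuals, prediction heads.

test_that("hard activations match their defining piecewise forms", {
  expect_equal(hswish(0), 0)
  expect_equal(hswish(3), 3)
  expect_equal(hswish(-3), 0)
  expect_equal(hswish(1), 4 / 6)
  expect_equal(hswish(10), 10)      # identity above 3
  expect_equal(hswish(-10), 0)      # zero below -3
  expect_equal(min(hswish(seq(-5, 5, by = 1e-3))), -3 / 8, tolerance = 1e-6)
  expect_equal(swish(0), 0)
  expect_equal(swish(2), 2 / (1 + exp(-2)))
  expect_equal(swish(30), 30, tolerance = 1e-9)
  expect_equal(hsigmoid(c(-3, 0, 3)), c(0, 0.5, 1))
})

test_that("hswish approximates swish within the analytic bound", {
  x <- seq(-10, 10, by = 1e-3)
  d <- abs(hswish(x) - swish(x))
  # the supremum of |hswish - swish| is 3*sigmoid(-3), attained at x = +-3
  expect_equal(max(d), 3 * plogis(-3), tolerance = 1e-6)
  expect_lte(max(d), 0.1423)
  expect_lt(max(abs(hswish(c(-10, 10)) - swish(c(-10, 10)))), 1e-3)
})

test_that("SPPF window parameters cover the input exactly", {
  p <- sppWindowParams(8, 8)
  expect_equal(c(p$k, p$s, p$p), c(1, 1, 0))
  p <- sppWindowParams(13, 4)
  expect_equal(c(p$k, p$s, p$p), c(4, 4, 2))
  p <- sppWindowParams(6, 3)
  expect_equal(c(p$k, p$s, p$p), c(2, 2, 0))
  expect_error(sppWindowParams(4, 8), "exceed")
  expect_error(sppWindowParams(0, 0), "positive")
  # exhaustive sweep: pooling with (k, s, p) yields exactly n output
  # positions and covers all w inputs
  for (w in 1:64) for (n in 1:w) {
    q <- sppWindowParams(w, n)
    n_out <- floor((w + 2 * q$p - q$k) / q$s) + 1
    expect_equal(n_out, n)
    expect_lte(q$s * (n - 1) + q$k, w + 2 * q$p)
  }
})

test_that("serial SPPF pooling equals parallel SPP with windows 5/9/13", {
  set.seed(101)
  for (rep in 1:20) {
    x <- array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
    serial <- sppfPool(x, 5L)
    parallel <- sppPool(x, c(5L, 9L, 13L))
    expect_equal(serial, parallel, tolerance = 1e-12)
  }
  # full SPPF: output spatial dims equal input; constant input stays
  # constant through the pooling stage
  x <- array(rnorm(12 * 12 * 4), c(12, 12, 4, 1))
  y <- sppfForward(x, hiddenChannels = 4L, seed = 3)
  expect_equal(dim(y)[1:2], c(12L, 12L))
  const <- array(2.5, c(8, 8, 2, 1))
  expect_true(all(sppfPool(const, 5L) == 2.5))
  expect_error(sppfForward(x, 4L, poolWindow = 4L), "odd")
})

test_that("squeeze-excitation gates channels within [0, 1]", {
  set.seed(7)
  x <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  y <- squeezeExcite(x, reduction = 4L, seed = 5)
  expect_equal(dim(y), dim(x))
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  # zero bottleneck weights -> gate = hsigmoid(0) = 0.5 -> output = x/2
  p <- sectornet:::init_se(8)
  p$w1[] <- 0; p$b1[] <- 0; p$w2[] <- 0; p$b2[] <- 0
  expect_equal(sectornet:::se_fwd(p, x)$y, x / 2)
  expect_error(squeezeExcite(x, reduction = 0L), "positive")
})

test_that("inverted residual blocks follow stride and shortcut rules", {
  cfg1 <- list(kernel = 3L, exp = 16L, cout = 8L, se = TRUE,
               act = "hswish", stride = 2L)
  x <- array(rnorm(64 * 64 * 8), c(64, 64, 8, 1))
  y <- invertedResidual(x, cfg1, seed = 2)
  expect_equal(dim(y), c(32L, 32L, 8L, 1L))
  # stride 1, in = out: output differs from the branch by exactly x
  cfg2 <- list(kernel = 3L, exp = 16L, cout = 8L, se = FALSE,
               act = "relu", stride = 1L)
  p <- local({ set.seed(9); sectornet:::init_bneck(8, cfg2) })
  expect_true(p$shortcut)
  with_sc <- sectornet:::bneck_fwd(p, x, train = FALSE)$y
  p2 <- p; p2$shortcut <- FALSE
  without_sc <- sectornet:::bneck_fwd(p2, x, train = FALSE)$y
  expect_equal(with_sc - without_sc, x, tolerance = 1e-12)
  # closed-form parameter count equals enumeration of the built weights
  for (cfg in list(cfg1, cfg2,
                   list(kernel = 5L, exp = 24L, cout = 12L, se = TRUE,
                        act = "hswish", stride = 1L))) {
    p <- sectornet:::init_bneck(8, cfg)
    enum <- 0
    sectornet:::walk_params(p, character(), function(path, node) {
      enum <<- enum + length(node)
    })
    expect_equal(sectornet:::count_bneck(8, cfg), enum)
  }
})

test_that("prediction heads emit anchor-major attribute channels", {
  x <- array(rnorm(10 * 10 * 16), c(10, 10, 16, 1))
  y <- predictionHead(x, nAnchors = 3L, nClasses = 4L, seed = 4)
  expect_equal(dim(y), c(10L, 10L, 27L, 1L))
  y1 <- predictionHead(x, nAnchors = 3L, nClasses = 1L, seed = 4)
  expect_equal(dim(y1)[3], 18L)
})
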