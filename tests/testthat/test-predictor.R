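test_that("self-attention re-weighting matches a per-element oracle", {
  # d_f = 1: softmax over one element is 1, output equals input
  p1 <- list(H = matrix(1), W = matrix(1), b = 0)
  x1 <- matrix(c(-2, 0.5, 3))
  expect_equal(selfAttentionReweight(x1, p1), x1)

  # identity H, W and zero bias: alpha = softmax(tanh(x)) per row
  x <- matrix(c(0.2, -1, 2, 1.5, 0, -0.7), 2, byrow = TRUE)
  pI <- list(H = diag(3), W = diag(3), b = numeric(3))
  got <- selfAttentionReweight(x, pI, returnWeights = TRUE)
  for (i in 1:2) {
    a <- oracleSoftmax(tanh(x[i, ]))
    expect_lt(max(abs(got$weights[i, ] - a)), 1e-6)
    expect_lt(max(abs(got$output[i, ] - a * x[i, ])), 1e-6)
  }
})

test_that("self-attention weights are row-stochastic and damp the input", {
  set.seed(3)
  for (rep in 1:20) {
    d <- sample(2:6, 1)
    x <- matrix(rnorm(4 * d), 4)
    params <- list(H = matrix(rnorm(d * d), d), W = matrix(rnorm(d * d), d),
                   b = rnorm(d))
    res <- selfAttentionReweight(x, params, returnWeights = TRUE)
    expect_equal(rowSums(res$weights), rep(1, 4), tolerance = 1e-6)
    expect_true(all(abs(res$output) <= abs(x)))
    expect_equal(dim(res$output), dim(x))
  }
  expect_error(selfAttentionReweight(matrix(0, 2, 3),
                                     list(H = diag(2), W = diag(2),
                                          b = numeric(2))), "shape")
})

test_that("the MLP scorer evaluates Sigmoid(Linear(Relu(Linear(x))))", {
  # all-zero parameters: sigmoid(0) = 0.5 everywhere
  p0 <- list(W1 = matrix(0, 3, 4), b1 = numeric(4), W2 = matrix(0, 4, 1),
             b2 = 0)
  expect_equal(forwardScore(matrix(rnorm(6), 2), p0), c(0.5, 0.5))

  # hand evaluation: x = (1, -1), identity hidden, sum output
  p <- list(W1 = diag(2), b1 = numeric(2), W2 = matrix(1, 2, 1), b2 = 0)
  expect_equal(forwardScore(matrix(c(1, -1), 1), p), 1 / (1 + exp(-1)),
               tolerance = 1e-12)

  set.seed(4)
  pr <- list(W1 = matrix(rnorm(12), 3), b1 = rnorm(4),
             W2 = matrix(rnorm(4)), b2 = rnorm(1))
  sc <- forwardScore(matrix(rnorm(30), 10), pr)
  expect_true(all(sc > 0 & sc < 1))
  expect_error(forwardScore(matrix(c(1, NA), 1), p), "finite")
})

test_that("binary cross-entropy matches closed forms", {
  expect_equal(bceLoss(c(0.5, 0.5, 0.5), c(1, 0, 1)), log(2))
  expect_equal(bceLoss(c(0.8, 0.3), c(1, 0)), -(log(0.8) + log(0.7)) / 2)
  expect_equal(bceLoss(c(0.8, 0.3), c(1, 0)), 0.28990, tolerance = 1e-4)
  expect_lt(bceLoss(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  expect_error(bceLoss(c(0.5), c(1, 0)), "length")
})

test_that("analytic gradients match central finite differences for every group", {
  cfg <- trainConfig(nHeads = 2, dF = 6, hidden = 5, dropout = 0, seed = 3)
  set.seed(42)
  d <- 8
  Xgd <- matrix(rnorm(4 * d), 4)
  Xm <- matrix(rnorm(4 * d), 4)
  Xl <- matrix(rnorm(4 * d), 4)
  y <- c(1, 0, 1, 0)
  for (combo in c("GD", "GD+GMD+GLD")) {
    par <- hetfuse:::initModelParams(d, cfg, combo)
    res <- hetfuse:::fullLossGrad(par, combo, Xgd, Xm, Xl, y, cfg)
    eps <- 1e-6
    for (nm in names(par)) {
      g <- res$grads[[nm]]
      # probe a handful of coordinates per group to keep runtime low
      probe <- seq_len(min(length(par[[nm]]), 6L))
      for (j in probe) {
        p2 <- par
        p2[[nm]][j] <- p2[[nm]][j] + eps
        lp <- hetfuse:::fullLossGrad(p2, combo, Xgd, Xm, Xl, y, cfg)$loss
        p2[[nm]][j] <- p2[[nm]][j] - 2 * eps
        lm <- hetfuse:::fullLossGrad(p2, combo, Xgd, Xm, Xl, y, cfg)$loss
        fd <- (lp - lm) / (2 * eps)
        expect_lt(abs(fd - g[j]) / max(1e-8, abs(fd) + abs(g[j])), 1e-4)
      }
    }
  }
})

test_that("zero learning rate leaves parameters and loss history unchanged", {
  set.seed(9)
  d <- 8
  X <- matrix(rnorm(10 * d), 10)
  y <- rep(c(1, 0), 5)
  cfg <- trainConfig(learningRate = 0, epochs = 5, dropout = 0, nHeads = 2,
                     dF = 6, hidden = 4, standardize = FALSE, seed = 2)
  m <- trainModel(X, X, X, y, config = cfg)
  expect_equal(length(unique(round(lossHistory(m), 12))), 1L)
  init <- hetfuse:::initModelParams(d, cfg, "GD+GMD+GLD")
  expect_equal(m@params, init)
})

test_that("training overfits a separable toy set and predictions recover labels", {
  set.seed(7)
  n <- 20; e <- 2; d <- 4 * e
  y <- rep(c(1, 0), 10)
  X <- matrix(rnorm(n * d), n) + outer(y, rep(2, d))
  cfg <- trainConfig(epochs = 500, dF = 16, hidden = 32, nHeads = 2,
                     dropout = 0, batchSize = 20, seed = 1)
  m <- trainModel(X, X, X, y, config = cfg)
  expect_lt(tail(lossHistory(m), 1), 0.05)
  expect_equal(length(lossHistory(m)), 500L)
  sc <- predictScores(m, X, X, X)
  expect_gte(sum((sc > 0.5) == (y == 1)), 19L)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("training and prediction are deterministic given the seed", {
  set.seed(11)
  X <- matrix(rnorm(12 * 8), 12)
  y <- rep(c(1, 0), 6)
  cfg <- trainConfig(epochs = 10, nHeads = 2, dF = 8, hidden = 6, seed = 5)
  m1 <- trainModel(X, X, X, y, config = cfg)
  m2 <- trainModel(X, X, X, y, config = cfg)
  expect_identical(lossHistory(m1), lossHistory(m2))
  expect_identical(m1@params, m2@params)
  s1 <- predictScores(m1, X, X, X)
  s2 <- predictScores(m1, X, X, X)
  expect_identical(s1, s2)
})

test_that("prediction validates feature widths against the model", {
  set.seed(12)
  X <- matrix(rnorm(8 * 8), 8)
  y <- rep(c(1, 0), 4)
  cfg <- trainConfig(epochs = 2, nHeads = 2, dF = 4, hidden = 4, seed = 1)
  m <- trainModel(X, labels = y, config = cfg, combo = "GD")
  expect_error(predictScores(m, matrix(0, 2, 12)), "width")
})

test_that("model checkpoints round-trip through JSON", {
  set.seed(13)
  X <- matrix(rnorm(8 * 8), 8)
  y <- rep(c(1, 0), 4)
  cfg <- trainConfig(epochs = 3, nHeads = 2, dF = 4, hidden = 4, seed = 1)
  m <- trainModel(X, X, X, y, config = cfg)
  f <- tempfile(fileext = ".json")
  writeModel(m, f)
  m2 <- readModel(f)
  expect_equal(m2@combo, m@combo)
  expect_equal(m2@params, m@params, tolerance = 1e-12)
  expect_equal(predictScores(m2, X, X, X), predictScores(m, X, X, X),
               tolerance = 1e-12)
})
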