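# CNN-Transformer building blocks and training behavior.

ad <- function(name) get(name, asNamespace("fnirsEmotion"))

test_that("1D convolution reproduces the hand-summed sliding window", {
  # input [1,2,3,4], kernel [1,1], bias 0 -> [3,5,7]
  tape <- ad("adTape")()
  x <- ad("adNode")(tape, matrix(c(1, 2, 3, 4), 4, 1))
  w <- ad("adParam")(matrix(c(1, 1), 2, 1))
  b <- ad("adParam")(0)
  out <- ad("adConv1d")(tape, x, w, b, 1L, 4L, 2L)
  expect_equal(as.vector(out$value), c(3, 5, 7))
})

test_that("single-tap identity kernel with pool 1 passes input through, and ReLU clips", {
  tape <- ad("adTape")()
  xv <- matrix(c(-1, 2, -3, 4), 4, 1)
  x <- ad("adNode")(tape, xv)
  w <- ad("adParam")(matrix(1, 1, 1))
  b <- ad("adParam")(0)
  conv <- ad("adConv1d")(tape, x, w, b, 1L, 4L, 1L)
  pooled <- ad("adMaxPool")(tape, conv, 1L, 4L, 1L)
  expect_equal(pooled$value, xv)
  relu <- ad("adRelu")(tape, pooled)
  expect_true(all(relu$value >= 0))
  expect_equal(as.vector(relu$value), c(0, 2, 0, 4))
})

test_that("attention with identity projections matches the hand-evaluated toy", {
  # X = I2, Q = K = V = X, dk = 2; Z frozen from an independent softmax
  # evaluation performed before the build
  tape <- ad("adTape")()
  X <- diag(2)
  x <- ad("adNode")(tape, X)
  q <- ad("adMatmul")(tape, x, ad("adParam")(diag(2)))
  k <- ad("adMatmul")(tape, x, ad("adParam")(diag(2)))
  v <- ad("adMatmul")(tape, x, ad("adParam")(diag(2)))
  sc <- ad("adScale")(tape, ad("adBmm")(tape, q, k, 1L, TRUE), 1 / sqrt(2))
  wt <- ad("adSoftmaxRows")(tape, sc)
  z <- ad("adBmm")(tape, wt, v, 1L)
  expected <- rbind(c(0.669761549326657, 0.330238450673343),
                    c(0.330238450673343, 0.669761549326657))
  expect_equal(z$value, expected, tolerance = 1e-6)
  expect_equal(rowSums(wt$value), c(1, 1), tolerance = 1e-6)
})

test_that("attention weight rows sum to 1 for random inputs", {
  set.seed(5)
  tape <- ad("adTape")()
  x <- ad("adNode")(tape, matrix(rnorm(60), 12, 5))  # 2 samples x 6 steps
  sc <- ad("adScale")(tape, ad("adBmm")(tape, x, x, 2L, TRUE), 1 / sqrt(5))
  wt <- ad("adSoftmaxRows")(tape, sc)
  expect_equal(rowSums(wt$value), rep(1, 12), tolerance = 1e-6)
})

test_that("a length-1 sequence returns its value projection exactly", {
  set.seed(6)
  X <- matrix(rnorm(4), 1, 4)
  Wv <- matrix(rnorm(16), 4, 4)
  tape <- ad("adTape")()
  x <- ad("adNode")(tape, X)
  q <- ad("adMatmul")(tape, x, ad("adParam")(matrix(rnorm(16), 4, 4)))
  k <- ad("adMatmul")(tape, x, ad("adParam")(matrix(rnorm(16), 4, 4)))
  v <- ad("adMatmul")(tape, x, ad("adParam")(Wv))
  sc <- ad("adScale")(tape, ad("adBmm")(tape, q, k, 1L, TRUE), 1 / 2)
  wt <- ad("adSoftmaxRows")(tape, sc)
  z <- ad("adBmm")(tape, wt, v, 1L)
  expect_equal(z$value, X %*% Wv, tolerance = 1e-12)
})

test_that("multi-head attention reduces to single-head and keeps shape", {
  set.seed(7)
  d <- 8L; L <- 5L
  X <- matrix(rnorm(L * d), L, d)
  mkParams <- function() {
    p <- new.env()
    p$Wq <- ad("adParam")(matrix(rnorm(d * d) * 0.3, d, d)); p$bq <- ad("adParam")(numeric(d))
    p$Wk <- ad("adParam")(matrix(rnorm(d * d) * 0.3, d, d)); p$bk <- ad("adParam")(numeric(d))
    p$Wv <- ad("adParam")(matrix(rnorm(d * d) * 0.3, d, d)); p$bv <- ad("adParam")(numeric(d))
    p$Wo <- ad("adParam")(diag(d)); p$bo <- ad("adParam")(numeric(d))
    p
  }
  p <- mkParams()
  tape <- ad("adTape")()
  x <- ad("adNode")(tape, X)
  one <- ad(".multiHeadAttention")(tape, x, p, 1L, L, 1L)
  # manual single-head computation with the same projections
  Q <- X %*% p$Wq$value; K <- X %*% p$Wk$value; V <- X %*% p$Wv$value
  S <- Q %*% t(K) / sqrt(d)
  W <- exp(S - apply(S, 1, max)); W <- W / rowSums(W)
  expect_equal(one$value, W %*% V, tolerance = 1e-10)
  # two heads: shape preserved, matches per-head brute force + concat
  tape2 <- ad("adTape")()
  x2 <- ad("adNode")(tape2, X)
  two <- ad(".multiHeadAttention")(tape2, x2, p, 1L, L, 2L)
  expect_identical(dim(two$value), c(L, d))
  dk <- d / 2
  manual <- do.call(cbind, lapply(1:2, function(h) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    S <- Q[, idx] %*% t(K[, idx]) / sqrt(dk)
    Wh <- exp(S - apply(S, 1, max)); Wh <- Wh / rowSums(Wh)
    Wh %*% V[, idx]
  }))
  expect_equal(two$value, manual, tolerance = 1e-10)
})

test_that("feed-forward core matches a hand-computed toy and zeros propagate", {
  # FFN(Z) = ReLU(Z W1 + b1) W2 + b2 on a 1 x 2 toy
  Z <- matrix(c(1, 2), 1, 2)
  W1 <- rbind(c(1, -1), c(2, 0)); b1 <- c(0.5, -3)
  W2 <- rbind(c(1, 1), c(-1, 2)); b2 <- c(0, 1)
  tape <- ad("adTape")()
  z <- ad("adNode")(tape, Z)
  ffn <- ad("adBias")(tape, ad("adMatmul")(
    tape, ad("adRelu")(tape, ad("adBias")(tape, ad("adMatmul")(tape, z, ad("adParam")(W1)),
                                          ad("adParam")(b1))),
    ad("adParam")(W2)), ad("adParam")(b2))
  # hand: ZW1 = [5, -1]; +b1 = [5.5, -4]; ReLU = [5.5, 0]; W2 -> [5.5, 5.5]; +b2
  expect_equal(as.vector(ffn$value), c(5.5, 6.5), tolerance = 1e-12)
  # zero input and biases give zero
  tape2 <- ad("adTape")()
  z0 <- ad("adNode")(tape2, matrix(0, 1, 2))
  ffn0 <- ad("adMatmul")(tape2, ad("adRelu")(tape2, ad("adMatmul")(tape2, z0, ad("adParam")(W1))),
                         ad("adParam")(W2))
  expect_true(all(ffn0$value == 0))
})

test_that("layer normalization standardizes each position before rescale", {
  set.seed(8)
  tape <- ad("adTape")()
  x <- ad("adNode")(tape, matrix(rnorm(40, mean = 3, sd = 2), 5, 8))
  y <- ad("adLayerNorm")(tape, x, ad("adParam")(rep(1, 8)), ad("adParam")(numeric(8)))
  expect_equal(rowMeans(y$value), rep(0, 5), tolerance = 1e-6)
  expect_equal(apply(y$value, 1, function(r) mean(r^2)), rep(1, 5),
               tolerance = 1e-3)
})

test_that("the default architecture traces (300,16) -> (29,32) -> 928 -> 3", {
  m <- buildCnnTransformer(seed = 1)
  tr <- forwardTrace(m)
  expect_equal(tr$input, c(300, 16))
  expect_equal(tr$transformer_input, c(29, 32))
  expect_equal(tr$flatten, 928)
  expect_equal(tr$output, 3)
  # analytic trace agrees
  ct <- convTrace(architectureConfig())
  expect_identical(unname(ct["pool2"]), 29L)
  expect_identical(unname(ct["flatten"]), 928L)
})

test_that("flatten width always equals final sequence length x filters", {
  for (cfg in list(architectureConfig(),
                   architectureConfig(inputLen = 240L, kernel1 = 6L),
                   tinyArch())) {
    ct <- convTrace(cfg)
    expect_identical(unname(ct["flatten"]),
                     unname(ct["pool2"] * cfg@convFilters))
  }
})

test_that("invalid architectures are rejected at build time naming the layer", {
  expect_error(architectureConfig(embedDim = 30L, numHeads = 4L), "divisible")
  expect_error(architectureConfig(inputLen = 6L), "conv layer 1")
  expect_error(architectureConfig(inputLen = 30L), "conv layer 2")
})

test_that("softmax outputs are probabilities summing to 1", {
  m <- buildCnnTransformer(tinyArch(), seed = 3)
  ds <- separableWindows(6, len = 30L)
  p <- predictProba(m, ds)
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # argmax consistency with predicted labels
  expect_identical(predictLabels(m, ds),
                   max.col(p, ties.method = "first") - 1L)
})

test_that("the model overfits a small strongly separable set", {
  ds <- separableWindows(30, len = 30L, gap = 3)
  arch <- tinyArch()
  arch@dropout <- 0   # exact memorization check, no stochastic regularizer
  m <- buildCnnTransformer(arch, seed = 4)
  m <- trainModel(m, ds, trainConfig(epochs = 100L, batchSize = 8L, seed = 4))
  hist <- trainingHistory(m)
  expect_equal(nrow(hist), 100L)
  expect_equal(utils::tail(hist$accuracy, 1), 1)            # 100% training accuracy
  expect_lt(utils::tail(hist$loss, 1), hist$loss[1])        # loss decreased
  expect_identical(predictLabels(m, ds), windowLabels(ds))  # test on itself
})

test_that("training is deterministic under a fixed seed", {
  ds <- separableWindows(18, len = 30L)
  fit <- function() {
    m <- buildCnnTransformer(tinyArch(), seed = 9)
    m <- trainModel(m, ds, trainConfig(epochs = 5L, batchSize = 6L, seed = 9))
    utils::tail(trainingHistory(m)$loss, 1)
  }
  expect_identical(fit(), fit())
})

test_that("training rejects bad inputs", {
  ds <- separableWindows(10, len = 30L)
  m <- buildCnnTransformer(tinyArch(), seed = 1)
  bad <- ds
  bad@labels[1] <- 5L
  expect_error(trainModel(m, bad, trainConfig(epochs = 1L)), "labels|valid")
  wrong <- separableWindows(10, len = 40L)
  expect_error(trainModel(m, wrong, trainConfig(epochs = 1L)),
               "does not match the architecture")
})

test_that("the network is sensitive to time order of a discriminative input", {
  set.seed(10)
  m <- buildCnnTransformer(tinyArch(), seed = 11)
  w <- matrix(rnorm(30 * 16), 30, 16) + outer(seq_len(30) / 10, rep(1, 16))
  ds1 <- windowDataset(list(w), 0L)
  ds2 <- windowDataset(list(w[sample(30), ]), 0L)
  expect_gt(max(abs(predictProba(m, ds1) - predictProba(m, ds2))), 1e-8)
})
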