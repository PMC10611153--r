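# Numerical gradient checks of the hand-rolled network blocks: analytic
# (reverse-mode) gradients must agree with central finite differences on
# miniature versions of every block.

ad <- function(name) get(name, asNamespace("fnirsEmotion"))

numGrad <- function(fn, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps; xm[i] <- x[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

test_that("conv + maxpool + flatten gradients match finite differences", {
  set.seed(1)
  nb <- 2L; L <- 7L; C <- 3L; k <- 3L; Fo <- 2L
  X <- matrix(rnorm(nb * L * C), nb * L, C)
  W0 <- matrix(rnorm(k * C * Fo) * 0.5, k * C, Fo)
  b0 <- rnorm(Fo)
  labs <- c(0L, 1L)
  lossAt <- function(Wv, ret = "value") {
    tape <- ad("adTape")()
    x <- ad("adNode")(tape, X)
    w <- ad("adParam")(matrix(Wv, k * C, Fo))
    b <- ad("adParam")(b0)
    h <- ad("adConv1d")(tape, x, w, b, nb, L, k)
    h <- ad("adMaxPool")(tape, h, nb, L - k + 1L, 2L)
    fl <- ad("adFlatten")(tape, h, nb, (L - k + 1L) %/% 2L)
    head <- ad("adParam")(diag(1, ncol(fl$value), 3))
    loss <- ad("adSoftmaxCrossEntropy")(
      tape, ad("adMatmul")(tape, fl, head), labs)
    if (ret == "value") return(loss$value)
    ad("adBackward")(tape, loss)
    w$grad
  }
  analytic <- lossAt(as.vector(W0), ret = "grad")
  numeric <- matrix(numGrad(function(v) lossAt(v), as.vector(W0)), k * C, Fo)
  expect_lt(max(abs(analytic - numeric)), 1e-7)
})

test_that("batch-norm and layer-norm input gradients match finite differences", {
  set.seed(2)
  X <- matrix(rnorm(15), 5, 3)
  G <- rnorm(3); B <- rnorm(3)
  labs <- c(0L, 1L, 2L, 0L, 1L)
  for (norm in c("adBatchNorm", "adLayerNorm")) {
    lossAt <- function(Xv, ret = "value") {
      tape <- ad("adTape")()
      x <- ad("adNode")(tape, matrix(Xv, 5, 3))
      g <- ad("adParam")(G); be <- ad("adParam")(B)
      y <- if (norm == "adBatchNorm") {
        ad("adBatchNorm")(tape, x, g, be, ad(".bnState")(3), TRUE)
      } else ad("adLayerNorm")(tape, x, g, be)
      loss <- ad("adSoftmaxCrossEntropy")(tape, y, labs)
      if (ret == "value") return(loss$value)
      ad("adBackward")(tape, loss)
      x$grad
    }
    analytic <- lossAt(as.vector(X), ret = "grad")
    numeric <- matrix(numGrad(function(v) lossAt(v), as.vector(X)), 5, 3)
    expect_lt(max(abs(analytic - numeric)), 1e-7)
  }
})

test_that("scaled dot-product attention input gradient matches finite differences", {
  set.seed(3)
  nb <- 2L; L <- 3L; d <- 4L
  X <- matrix(rnorm(nb * L * d), nb * L, d)
  Wq <- matrix(rnorm(d * d) * 0.5, d, d)
  Wk <- matrix(rnorm(d * d) * 0.5, d, d)
  Wv <- matrix(rnorm(d * d) * 0.5, d, d)
  labs <- c(0L, 2L)
  lossAt <- function(Xv, ret = "value") {
    tape <- ad("adTape")()
    x <- ad("adNode")(tape, matrix(Xv, nb * L, d))
    q <- ad("adMatmul")(tape, x, ad("adParam")(Wq))
    k <- ad("adMatmul")(tape, x, ad("adParam")(Wk))
    v <- ad("adMatmul")(tape, x, ad("adParam")(Wv))
    sc <- ad("adScale")(tape, ad("adBmm")(tape, q, k, nb, TRUE), 1 / sqrt(d))
    wt <- ad("adSoftmaxRows")(tape, sc)
    z <- ad("adBmm")(tape, wt, v, nb)
    fl <- ad("adFlatten")(tape, z, nb, L)
    loss <- ad("adSoftmaxCrossEntropy")(
      tape, ad("adMatmul")(tape, fl, ad("adParam")(diag(1, L * d, 3))), labs)
    if (ret == "value") return(loss$value)
    ad("adBackward")(tape, loss)
    x$grad
  }
  analytic <- lossAt(as.vector(X), ret = "grad")
  numeric <- matrix(numGrad(function(v) lossAt(v), as.vector(X)), nb * L, d)
  expect_lt(max(abs(analytic - numeric)), 1e-7)
})

test_that("LSTM cell gate gradients match finite differences", {
  set.seed(4)
  C <- 3L; H <- 2L; nb <- 2L
  X <- matrix(rnorm(nb * C), nb, C)
  Wx0 <- matrix(rnorm(C * 4 * H) * 0.5, C, 4 * H)
  Wh0 <- matrix(rnorm(H * 4 * H) * 0.5, H, 4 * H)
  b0 <- rnorm(4 * H)
  labs <- c(0L, 1L)
  lossAt <- function(Wv, ret = "value") {
    tape <- ad("adTape")()
    x <- ad("adNode")(tape, X)
    h <- ad("adNode")(tape, matrix(0, nb, H))
    cc <- ad("adNode")(tape, matrix(0, nb, H))
    wx <- ad("adParam")(matrix(Wv, C, 4 * H))
    gates <- ad("adAdd")(tape, ad("adMatmul")(tape, x, wx),
                         ad("adBias")(tape, ad("adMatmul")(tape, h, ad("adParam")(Wh0)),
                                      ad("adParam")(b0)))
    ig <- ad("adSigmoid")(tape, ad("adCols")(tape, gates, 1:H))
    fg <- ad("adSigmoid")(tape, ad("adCols")(tape, gates, (H + 1):(2 * H)))
    og <- ad("adSigmoid")(tape, ad("adCols")(tape, gates, (2 * H + 1):(3 * H)))
    gg <- ad("adTanh")(tape, ad("adCols")(tape, gates, (3 * H + 1):(4 * H)))
    cc <- ad("adAdd")(tape, ad("adMul")(tape, fg, cc), ad("adMul")(tape, ig, gg))
    h <- ad("adMul")(tape, og, ad("adTanh")(tape, cc))
    loss <- ad("adSoftmaxCrossEntropy")(
      tape, ad("adMatmul")(tape, h, ad("adParam")(diag(1, H, 3))), labs)
    if (ret == "value") return(loss$value)
    ad("adBackward")(tape, loss)
    wx$grad
  }
  analytic <- lossAt(as.vector(Wx0), ret = "grad")
  numeric <- matrix(numGrad(function(v) lossAt(v), as.vector(Wx0)), C, 4 * H)
  expect_lt(max(abs(analytic - numeric)), 1e-7)
})
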