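#' @include autodiff.R
NULL

#' Trained neural sequence classifier
#'
#' Shared container for the CNN-Transformer and the neural reference models
#' (plain CNN, LSTM, Transformer). Parameters and batch-norm running
#' statistics live in environments so training updates in place.
#'
#' @slot kind One of `"cnn_transformer"`, `"cnn"`, `"lstm"`, `"transformer"`.
#' @slot arch The [ArchitectureConfig-class] (field meanings depend on kind).
#' @slot params Environment of parameter leaf nodes.
#' @slot state Environment of non-trained state (batch-norm running
#'   statistics, training history).
#' @export
setClass("NeuralModel",
  representation(kind = "character", arch = "ArchitectureConfig",
                 params = "environment", state = "environment"))

setMethod("show", "NeuralModel", function(object) {
  np <- sum(vapply(as.list(object@params), function(p) length(p$value), numeric(1)))
  cat(sprintf("NeuralModel '%s', %d parameters\n", object@kind, np))
  if (!is.null(object@state$history))
    cat(sprintf("  trained %d epochs, final loss %.4f, final train accuracy %.3f\n",
                nrow(object@state$history),
                utils::tail(object@state$history$loss, 1),
                utils::tail(object@state$history$accuracy, 1)))
})

.bnState <- function(dim) {
  e <- new.env(parent = emptyenv())
  e$mean <- numeric(dim)
  e$var <- rep(1, dim)
  e
}

## ----- parameter initialization ---------------------------------------------

.initCnnTransformer <- function(arch) {
  p <- new.env(parent = emptyenv())
  C <- arch@inputFeatures; F1 <- arch@convFilters
  d <- arch@embedDim
  tr <- convTrace(arch)
  p$convW1 <- adParam(glorotUniform(arch@kernel1 * C, F1, c(arch@kernel1 * C, F1)))
  p$convB1 <- adParam(numeric(F1))
  p$bnG1 <- adParam(rep(1, F1)); p$bnB1 <- adParam(numeric(F1))
  p$convW2 <- adParam(glorotUniform(arch@kernel2 * F1, F1, c(arch@kernel2 * F1, F1)))
  p$convB2 <- adParam(numeric(F1))
  p$bnG2 <- adParam(rep(1, F1)); p$bnB2 <- adParam(numeric(F1))
  p$embedW <- adParam(glorotUniform(F1, d)); p$embedB <- adParam(numeric(d))
  p$Wq <- adParam(glorotUniform(d, d)); p$bq <- adParam(numeric(d))
  p$Wk <- adParam(glorotUniform(d, d)); p$bk <- adParam(numeric(d))
  p$Wv <- adParam(glorotUniform(d, d)); p$bv <- adParam(numeric(d))
  p$Wo <- adParam(glorotUniform(d, d)); p$bo <- adParam(numeric(d))
  p$lnG1 <- adParam(rep(1, d)); p$lnB1 <- adParam(numeric(d))
  p$ffW1 <- adParam(glorotUniform(d, arch@ffDim)); p$ffB1 <- adParam(numeric(arch@ffDim))
  p$ffW2 <- adParam(glorotUniform(arch@ffDim, d)); p$ffB2 <- adParam(numeric(d))
  p$lnG2 <- adParam(rep(1, d)); p$lnB2 <- adParam(numeric(d))
  # flatten width after the transformer is (final sequence length x embedDim)
  p$headW1 <- adParam(glorotUniform(tr[["pool2"]] * d, arch@headDense))
  p$headB1 <- adParam(numeric(arch@headDense))
  p$headW2 <- adParam(glorotUniform(arch@headDense, arch@nClasses))
  p$headB2 <- adParam(numeric(arch@nClasses))
  p
}

## ----- building blocks -------------------------------------------------------

## conv -> batch norm -> ReLU -> max pool; returns list(node, length)
.convBlock <- function(tape, x, w, b, gamma, beta, bn, nb, L, k, pool, training,
                       inputGrad = TRUE) {
  h <- adConv1d(tape, x, w, b, nb, L, k, inputGrad = inputGrad)
  Lc <- L - k + 1L
  h <- adBatchNorm(tape, h, gamma, beta, bn, training)
  h <- adRelu(tape, h)
  h <- adMaxPool(tape, h, nb, Lc, pool)
  list(node = h, len = Lc %/% pool)
}

## Multi-head scaled dot-product self-attention, heads as contiguous column
## slices of the d-dimensional projections.
.multiHeadAttention <- function(tape, x, p, nb, L, numHeads) {
  d <- ncol(p$Wq$value)
  dk <- d %/% numHeads
  q <- adBias(tape, adMatmul(tape, x, p$Wq), p$bq)
  k <- adBias(tape, adMatmul(tape, x, p$Wk), p$bk)
  v <- adBias(tape, adMatmul(tape, x, p$Wv), p$bv)
  heads <- vector("list", numHeads)
  for (h in seq_len(numHeads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    qh <- adCols(tape, q, idx)
    kh <- adCols(tape, k, idx)
    vh <- adCols(tape, v, idx)
    scores <- adScale(tape, adBmm(tape, qh, kh, nb, transposeB = TRUE),
                      1 / sqrt(dk))
    weights <- adSoftmaxRows(tape, scores)
    heads[[h]] <- adBmm(tape, weights, vh, nb)
  }
  concat <- if (numHeads == 1L) heads[[1]] else adConcatCols(tape, heads)
  adBias(tape, adMatmul(tape, concat, p$Wo), p$bo)
}

## Transformer block: MHA + residual/layer norm, FFN + residual/layer norm.
.transformerBlock <- function(tape, x, p, nb, L, numHeads) {
  att <- .multiHeadAttention(tape, x, p, nb, L, numHeads)
  z <- adLayerNorm(tape, adAdd(tape, x, att), p$lnG1, p$lnB1)
  ff <- adBias(tape, adMatmul(
    tape, adRelu(tape, adBias(tape, adMatmul(tape, z, p$ffW1), p$ffB1)),
    p$ffW2), p$ffB2)
  adLayerNorm(tape, adAdd(tape, z, ff), p$lnG2, p$lnB2)
}

## Forward pass of the CNN-Transformer. X is the stacked batch
## ((nb * inputLen) x inputFeatures). Returns the logits node; when
## trace is TRUE also records the shape entering each stage.
.forwardCnnTransformer <- function(tape, p, st, X, nb, arch, training,
                                   trace = NULL) {
  x <- adNode(tape, X)
  L <- arch@inputLen
  if (!is.null(trace)) trace$input <- c(L, ncol(X))
  b1 <- .convBlock(tape, x, p$convW1, p$convB1, p$bnG1, p$bnB1, st$bn1,
                   nb, L, arch@kernel1, arch@poolSize, training,
                   inputGrad = FALSE)
  b2 <- .convBlock(tape, b1$node, p$convW2, p$convB2, p$bnG2, p$bnB2, st$bn2,
                   nb, b1$len, arch@kernel2, arch@poolSize, training)
  Lt <- b2$len
  h <- adBias(tape, adMatmul(tape, b2$node, p$embedW), p$embedB)
  if (!is.null(trace)) trace$transformer_input <- c(Lt, ncol(h$value))
  h <- .transformerBlock(tape, h, p, nb, Lt, arch@numHeads)
  flat <- adFlatten(tape, h, nb, Lt)
  if (!is.null(trace)) trace$flatten <- ncol(flat$value)
  flat <- adDropout(tape, flat, arch@dropout, training)
  d1 <- adRelu(tape, adBias(tape, adMatmul(tape, flat, p$headW1), p$headB1))
  adBias(tape, adMatmul(tape, d1, p$headW2), p$headB2)
}

## ----- public API -------------------------------------------------------------

#' Build the CNN-Transformer classifier
#'
#' Instantiates the network with freshly initialized weights (Glorot
#' uniform, seeded). Architecture: two conv-BN-ReLU-maxpool blocks, a
#' position-wise dense embedding, one Transformer block (multi-head
#' self-attention and feed-forward sublayers, each wrapped in residual add +
#' layer norm), flatten, dropout, a ReLU dense layer and a softmax head.
#' Under the default configuration the shape trace is
#' (300, 16) -> (29, 32) -> (29, 32) -> 928 -> 500 -> 3.
#'
#' @param arch An [ArchitectureConfig-class].
#' @param seed Seed for weight initialization.
#' @return A [NeuralModel-class] of kind `"cnn_transformer"`.
#' @export
buildCnnTransformer <- function(arch = architectureConfig(), seed = 1L) {
  methods::validObject(arch)
  set.seed(as.integer(seed))
  st <- new.env(parent = emptyenv())
  st$bn1 <- .bnState(arch@convFilters)
  st$bn2 <- .bnState(arch@convFilters)
  new("NeuralModel", kind = "cnn_transformer", arch = arch,
      params = .initCnnTransformer(arch), state = st)
}

#' Shape trace of a forward pass
#'
#' Runs one window (or a whole dataset) through the model in inference mode
#' and reports the actual tensor shapes at the documented checkpoints:
#' the input, the (time steps, features) shape entering the Transformer
#' block, the flattened width, and the output class count.
#'
#' @param model A [NeuralModel-class].
#' @param window A windowLength x 16 matrix (defaults to zeros of the
#'   configured shape).
#' @return Named list: `input`, `transformer_input`, `flatten`, `output`.
#' @export
forwardTrace <- function(model, window = NULL) {
  arch <- model@arch
  if (is.null(window))
    window <- matrix(0, arch@inputLen, arch@inputFeatures)
  stopifnot(nrow(window) == arch@inputLen,
            ncol(window) == arch@inputFeatures)
  trace <- new.env()
  tape <- adTape()
  logits <- .forwardNet(tape, model, window, 1L, training = FALSE,
                        trace = trace)
  out <- as.list(trace)
  out$output <- ncol(logits$value)
  out[c("input", "transformer_input", "flatten", "output")]
}

## dispatch over network kinds (shared by training and prediction)
.forwardNet <- function(tape, model, X, nb, training, trace = NULL) {
  switch(model@kind,
    cnn_transformer = .forwardCnnTransformer(tape, model@params, model@state,
                                             X, nb, model@arch, training, trace),
    cnn = .forwardCnn(tape, model@params, model@state, X, nb, model@arch,
                      training, trace),
    transformer = .forwardTransformerNet(tape, model@params, X, nb,
                                         model@arch, training, trace),
    lstm = .forwardLstm(tape, model@params, X, nb, model@arch, training),
    stop("unknown network kind: ", model@kind))
}

#' Train a neural model by mini-batch SGD on cross-entropy
#'
#' Plain stochastic gradient descent (no momentum), categorical
#' cross-entropy loss, shuffled mini-batches. The per-epoch mean training
#' loss and training accuracy are recorded in the model's history.
#' Reproducible: the same seed, data and configuration give identical
#' weights.
#'
#' @param model A [NeuralModel-class] (modified in place and returned).
#' @param ds Training [WindowDataset-class]; window shape must match the
#'   architecture.
#' @param cfg A [TrainConfig-class].
#' @param verbose Print a line every `verbose` epochs (0 = silent).
#' @return The trained model, invisibly also carrying
#'   `model@state$history` (data.frame epoch/loss/accuracy).
#' @export
trainModel <- function(model, ds, cfg = trainConfig(), verbose = 0L) {
  n <- nWindows(ds)
  if (n == 0L) stop("empty training dataset")
  if (!all(windowLabels(ds) %in% 0:2))
    stop("labels must be in {0,1,2}")
  arch <- model@arch
  if (windowLength(ds) != arch@inputLen ||
      ncol(ds@windows[[1]]) != arch@inputFeatures)
    stop(sprintf("window shape (%d x %d) does not match the architecture (%d x %d)",
                 windowLength(ds), ncol(ds@windows[[1]]),
                 arch@inputLen, arch@inputFeatures))
  X <- .stackWindows(ds)
  labels <- windowLabels(ds)
  L <- arch@inputLen
  set.seed(cfg@seed)
  params <- Filter(is.environment, as.list(model@params))
  hist <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  for (epoch in seq_len(cfg@epochs)) {
    perm <- sample.int(n)
    epochLoss <- 0; correct <- 0L
    nBatches <- ceiling(n / cfg@batchSize)
    for (bi in seq_len(nBatches)) {
      take <- perm[(((bi - 1L) * cfg@batchSize + 1L):min(bi * cfg@batchSize, n))]
      nb <- length(take)
      rows <- as.vector(outer(seq_len(L), (take - 1L) * L, "+"))
      tape <- adTape()
      logits <- .forwardNet(tape, model, X[rows, , drop = FALSE], nb,
                            training = TRUE)
      loss <- adSoftmaxCrossEntropy(tape, logits, labels[take])
      for (pp in params) pp$grad <- NULL
      adBackward(tape, loss)
      for (pp in params)
        if (!is.null(pp$grad)) pp$value <- pp$value - cfg@learningRate * pp$grad
      epochLoss <- epochLoss + loss$value * nb
      correct <- correct + sum(max.col(loss$probs, ties.method = "first") - 1L ==
                                 labels[take])
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = epochLoss / n,
                                   accuracy = correct / n))
    if (verbose > 0L && epoch %% verbose == 0L)
      message(sprintf("epoch %4d  loss %.4f  acc %.3f", epoch,
                      epochLoss / n, correct / n))
  }
  model@state$history <- hist
  invisible(model)
}

#' Training history of a fitted neural model
#' @param model A trained [NeuralModel-class].
#' @return Data frame with columns `epoch`, `loss`, `accuracy`.
#' @export
trainingHistory <- function(model) {
  if (is.null(model@state$history)) stop("model has not been trained")
  model@state$history
}

.predictProbaNeural <- function(model, ds, batchSize = 128L) {
  n <- nWindows(ds)
  X <- .stackWindows(ds)
  L <- model@arch@inputLen
  out <- matrix(0, n, model@arch@nClasses)
  for (start in seq(1L, n, by = batchSize)) {
    take <- start:min(start + batchSize - 1L, n)
    nb <- length(take)
    rows <- as.vector(outer(seq_len(L), (take - 1L) * L, "+"))
    tape <- adTape()
    logits <- .forwardNet(tape, model, X[rows, , drop = FALSE], nb,
                          training = FALSE)
    m <- logits$value - apply(logits$value, 1, max)
    e <- exp(m)
    out[take, ] <- e / rowSums(e)
  }
  colnames(out) <- as.character(seq_len(model@arch@nClasses) - 1L)
  out
}

#' @describeIn predictProba Softmax class probabilities of a neural model.
#' @export
setMethod("predictProba", "NeuralModel", function(object, newdata) {
  .predictProbaNeural(object, newdata)
})

#' @describeIn predictLabels Argmax of the softmax probabilities.
#' @export
setMethod("predictLabels", "NeuralModel", function(object, newdata) {
  max.col(.predictProbaNeural(object, newdata), ties.method = "first") - 1L
})
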