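#' @include model.R
NULL

## ---------------------------------------------------------------------------
## Neural reference networks sharing the autodiff engine.
## ---------------------------------------------------------------------------

## Plain CNN: the same conv front-end as the hybrid, then flatten ->
## dropout -> dense(headDense) -> softmax. No Transformer block.
.initCnn <- function(arch) {
  p <- new.env(parent = emptyenv())
  C <- arch@inputFeatures; F1 <- arch@convFilters
  tr <- convTrace(arch)
  p$convW1 <- adParam(glorotUniform(arch@kernel1 * C, F1, c(arch@kernel1 * C, F1)))
  p$convB1 <- adParam(numeric(F1))
  p$bnG1 <- adParam(rep(1, F1)); p$bnB1 <- adParam(numeric(F1))
  p$convW2 <- adParam(glorotUniform(arch@kernel2 * F1, F1, c(arch@kernel2 * F1, F1)))
  p$convB2 <- adParam(numeric(F1))
  p$bnG2 <- adParam(rep(1, F1)); p$bnB2 <- adParam(numeric(F1))
  p$headW1 <- adParam(glorotUniform(tr["flatten"], arch@headDense))
  p$headB1 <- adParam(numeric(arch@headDense))
  p$headW2 <- adParam(glorotUniform(arch@headDense, arch@nClasses))
  p$headB2 <- adParam(numeric(arch@nClasses))
  p
}

.forwardCnn <- function(tape, p, st, X, nb, arch, training, trace = NULL) {
  x <- adNode(tape, X)
  L <- arch@inputLen
  b1 <- .convBlock(tape, x, p$convW1, p$convB1, p$bnG1, p$bnB1, st$bn1,
                   nb, L, arch@kernel1, arch@poolSize, training,
                   inputGrad = FALSE)
  b2 <- .convBlock(tape, b1$node, p$convW2, p$convB2, p$bnG2, p$bnB2, st$bn2,
                   nb, b1$len, arch@kernel2, arch@poolSize, training)
  flat <- adFlatten(tape, b2$node, nb, b2$len)
  if (!is.null(trace)) trace$flatten <- ncol(flat$value)
  flat <- adDropout(tape, flat, arch@dropout, training)
  d1 <- adRelu(tape, adBias(tape, adMatmul(tape, flat, p$headW1), p$headB1))
  adBias(tape, adMatmul(tape, d1, p$headW2), p$headB2)
}

## Transformer-only: position-wise dense embedding of the raw window, one
## Transformer block, flatten -> dropout -> dense -> softmax.
.initTransformerNet <- function(arch) {
  p <- new.env(parent = emptyenv())
  d <- arch@embedDim
  p$embedW <- adParam(glorotUniform(arch@inputFeatures, d))
  p$embedB <- adParam(numeric(d))
  p$Wq <- adParam(glorotUniform(d, d)); p$bq <- adParam(numeric(d))
  p$Wk <- adParam(glorotUniform(d, d)); p$bk <- adParam(numeric(d))
  p$Wv <- adParam(glorotUniform(d, d)); p$bv <- adParam(numeric(d))
  p$Wo <- adParam(glorotUniform(d, d)); p$bo <- adParam(numeric(d))
  p$lnG1 <- adParam(rep(1, d)); p$lnB1 <- adParam(numeric(d))
  p$ffW1 <- adParam(glorotUniform(d, arch@ffDim)); p$ffB1 <- adParam(numeric(arch@ffDim))
  p$ffW2 <- adParam(glorotUniform(arch@ffDim, d)); p$ffB2 <- adParam(numeric(d))
  p$lnG2 <- adParam(rep(1, d)); p$lnB2 <- adParam(numeric(d))
  p$headW1 <- adParam(glorotUniform(arch@inputLen * d, arch@headDense))
  p$headB1 <- adParam(numeric(arch@headDense))
  p$headW2 <- adParam(glorotUniform(arch@headDense, arch@nClasses))
  p$headB2 <- adParam(numeric(arch@nClasses))
  p
}

.forwardTransformerNet <- function(tape, p, X, nb, arch, training,
                                   trace = NULL) {
  x <- adNode(tape, X)
  L <- arch@inputLen
  h <- adBias(tape, adMatmul(tape, x, p$embedW), p$embedB)
  if (!is.null(trace)) trace$transformer_input <- c(L, ncol(h$value))
  h <- .transformerBlock(tape, h, p, nb, L, arch@numHeads)
  flat <- adFlatten(tape, h, nb, L)
  flat <- adDropout(tape, flat, arch@dropout, training)
  d1 <- adRelu(tape, adBias(tape, adMatmul(tape, flat, p$headW1), p$headB1))
  adBias(tape, adMatmul(tape, d1, p$headW2), p$headB2)
}

## LSTM over the raw sequence; the final hidden state feeds the softmax head.
.initLstm <- function(arch, hidden = 32L) {
  p <- new.env(parent = emptyenv())
  C <- arch@inputFeatures
  p$hidden <- hidden
  p$Wx <- adParam(glorotUniform(C, 4L * hidden))
  p$Wh <- adParam(glorotUniform(hidden, 4L * hidden))
  b <- numeric(4L * hidden)
  b[(hidden + 1L):(2L * hidden)] <- 1  # forget-gate bias at 1
  p$b <- adParam(b)
  p$headW <- adParam(glorotUniform(hidden, arch@nClasses))
  p$headB <- adParam(numeric(arch@nClasses))
  p
}

.forwardLstm <- function(tape, p, X, nb, arch, training) {
  L <- arch@inputLen
  H <- p$hidden
  rowsOf <- function(t) (seq_len(nb) - 1L) * L + t
  h <- adNode(tape, matrix(0, nb, H))
  cc <- adNode(tape, matrix(0, nb, H))
  for (t in seq_len(L)) {
    xt <- adNode(tape, X[rowsOf(t), , drop = FALSE])
    gates <- adAdd(tape, adMatmul(tape, xt, p$Wx),
                   adBias(tape, adMatmul(tape, h, p$Wh), p$b))
    ig <- adSigmoid(tape, adCols(tape, gates, 1:H))
    fg <- adSigmoid(tape, adCols(tape, gates, (H + 1L):(2L * H)))
    og <- adSigmoid(tape, adCols(tape, gates, (2L * H + 1L):(3L * H)))
    gg <- adTanh(tape, adCols(tape, gates, (3L * H + 1L):(4L * H)))
    cc <- adAdd(tape, adMul(tape, fg, cc), adMul(tape, ig, gg))
    h <- adMul(tape, og, adTanh(tape, cc))
  }
  adBias(tape, adMatmul(tape, h, p$headW), p$headB)
}

#' Build a neural reference model
#'
#' @param kind `"cnn"`, `"lstm"` or `"transformer"`.
#' @param arch An [ArchitectureConfig-class]; the relevant fields are used by
#'   each kind.
#' @param seed Weight-initialization seed.
#' @param hidden LSTM hidden size.
#' @return A [NeuralModel-class].
#' @export
buildNeuralBaseline <- function(kind = c("cnn", "lstm", "transformer"),
                                arch = architectureConfig(), seed = 1L,
                                hidden = 32L) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  st <- new.env(parent = emptyenv())
  params <- switch(kind,
    cnn = {
      st$bn1 <- .bnState(arch@convFilters)
      st$bn2 <- .bnState(arch@convFilters)
      .initCnn(arch)
    },
    transformer = .initTransformerNet(arch),
    lstm = .initLstm(arch, hidden))
  new("NeuralModel", kind = kind, arch = arch, params = params, state = st)
}

## ---------------------------------------------------------------------------
## Uniform fitting interface over the nine classifiers.
## ---------------------------------------------------------------------------

.classifierNames <- c("decision_tree", "random_forest", "svm", "knn",
                      "xgboost", "cnn", "lstm", "transformer",
                      "cnn_transformer")

#' Fit any of the supported classifiers
#'
#' Classical models (`decision_tree`, `random_forest`, `svm`, `knn`,
#' `xgboost`) operate on flattened windows (one feature vector per window)
#' and use the backing library's defaults; the neural models (`cnn`, `lstm`,
#' `transformer`, `cnn_transformer`) keep the sequence structure and are
#' trained with SGD ([trainModel()]). Every fit is seeded.
#'
#' @param name One of `r paste(.classifierNames, collapse = ", ")`.
#' @param ds Training [WindowDataset-class].
#' @param seed RNG seed for the fit.
#' @param control Optional list of per-model settings: `epochs`,
#'   `learningRate`, `batchSize` (neural models), `k` (knn), `nrounds`
#'   (xgboost), `ntree` (random forest), `hidden` (lstm), `arch`
#'   (an [ArchitectureConfig-class] overriding the one derived from the
#'   window shape).
#' @return A [FittedClassifier-class].
#' @export
fitBaseline <- function(name, ds, seed = 1L, control = list()) {
  if (!name %in% .classifierNames)
    stop("unknown classifier '", name, "'; valid names: ",
         paste(.classifierNames, collapse = ", "))
  if (nWindows(ds) == 0L) stop("empty training dataset")
  set.seed(as.integer(seed))
  if (name %in% c("cnn", "lstm", "transformer", "cnn_transformer")) {
    arch <- control$arch
    if (is.null(arch))
      arch <- architectureConfig(inputLen = windowLength(ds),
                                 inputFeatures = ncol(ds@windows[[1]]))
    epochs <- if (is.null(control$epochs)) 100L else control$epochs
    lr <- if (is.null(control$learningRate)) 0.005 else control$learningRate
    bs <- if (is.null(control$batchSize)) 32L else control$batchSize
    model <- if (name == "cnn_transformer") {
      buildCnnTransformer(arch, seed = seed)
    } else {
      buildNeuralBaseline(name, arch, seed = seed,
                          hidden = if (is.null(control$hidden)) 32L else control$hidden)
    }
    model <- trainModel(model, ds,
                        trainConfig(learningRate = lr, batchSize = bs,
                                    epochs = epochs, seed = seed))
    return(new("FittedClassifier", name = name, fit = model,
               predictFun = function(fit, nd) predictLabels(fit, nd),
               probaFun = function(fit, nd) predictProba(fit, nd)))
  }
  X <- flattenWindows(ds)
  y <- windowLabels(ds)
  switch(name,
    decision_tree = {
      df <- data.frame(y = factor(y, levels = 0:2), X)
      fit <- rpart::rpart(y ~ ., data = df, method = "class")
      new("FittedClassifier", name = name, fit = fit,
          predictFun = function(fit, nd) {
            ndf <- data.frame(flattenWindows(nd))
            as.integer(as.character(predict(fit, ndf, type = "class")))
          },
          probaFun = function(fit, nd)
            predict(fit, data.frame(flattenWindows(nd)), type = "prob"))
    },
    random_forest = {
      ntree <- if (is.null(control$ntree)) 500L else control$ntree
      fit <- randomForest::randomForest(X, factor(y, levels = 0:2),
                                        ntree = ntree)
      new("FittedClassifier", name = name, fit = fit,
          predictFun = function(fit, nd)
            as.integer(as.character(predict(fit, flattenWindows(nd)))),
          probaFun = function(fit, nd)
            predict(fit, flattenWindows(nd), type = "prob"))
    },
    svm = {
      fit <- e1071::svm(X, factor(y, levels = 0:2))
      new("FittedClassifier", name = name, fit = fit,
          predictFun = function(fit, nd)
            as.integer(as.character(predict(fit, flattenWindows(nd)))),
          probaFun = NULL)
    },
    knn = {
      k <- if (is.null(control$k)) 5L else control$k
      fit <- list(X = X, y = y, k = k)
      new("FittedClassifier", name = name, fit = fit,
          predictFun = function(fit, nd)
            as.integer(as.character(class::knn(fit$X, flattenWindows(nd),
                                               factor(fit$y, levels = 0:2),
                                               k = fit$k))),
          probaFun = NULL)
    },
    xgboost = {
      nrounds <- if (is.null(control$nrounds)) 50L else control$nrounds
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = 3,
                      nthread = 1L, seed = as.integer(seed)),
        data = xgboost::xgb.DMatrix(X, label = y), nrounds = nrounds,
        verbose = 0)
      proba <- function(fit, nd) {
        p <- predict(fit, xgboost::xgb.DMatrix(flattenWindows(nd)))
        matrix(p, ncol = 3)
      }
      new("FittedClassifier", name = name, fit = fit,
          predictFun = function(fit, nd)
            max.col(proba(fit, nd), ties.method = "first") - 1L,
          probaFun = proba)
    })
}

#' Names of the supported classifiers
#' @return Character vector.
#' @export
classifierNames <- function() .classifierNames
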