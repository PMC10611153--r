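#' @include baselines.R
NULL

#' Confusion matrix and accuracy
#'
#' Tallies a 3x3 confusion matrix (rows = true class, columns = predicted;
#' classes 0 joy, 1 neutral, 2 sad) and the overall accuracy
#' (diagonal sum / total).
#'
#' @param truth,predicted Equal-length integer vectors over `{0,1,2}`.
#' @return List with elements `confusion` (3x3 integer matrix) and
#'   `accuracy`.
#' @export
confusionAndAccuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  if (!all(truth %in% 0:2) || !all(predicted %in% 0:2))
    stop("labels must be in {0,1,2}")
  cm <- matrix(0L, 3L, 3L,
               dimnames = list(true = c("joy", "neutral", "sad"),
                               predicted = c("joy", "neutral", "sad")))
  for (i in seq_along(truth))
    cm[truth[i] + 1L, predicted[i] + 1L] <- cm[truth[i] + 1L, predicted[i] + 1L] + 1L
  list(confusion = cm, accuracy = sum(diag(cm)) / length(truth))
}

#' Friedman rank test over classifiers
#'
#' Nonparametric comparison of k related samples: rows are runs (blocks),
#' columns are classifiers. Values are mid-ranked within each row and the
#' tie-corrected Friedman chi-square
#' \deqn{\chi^2_F = \frac{12 \sum_j (R_j - n(k+1)/2)^2}
#'   {n k (k+1) - \frac{1}{k-1}\sum_{rows}\sum_{ties}(t^3 - t)}}
#' is referred to a chi-square distribution with k-1 degrees of freedom.
#' Kendall's coefficient of concordance is \eqn{W = \chi^2_F / (n(k-1))} and
#' Cohen's effect size \eqn{f = \sqrt{W / (1 - W)}}.
#'
#' @param accMatrix Numeric n_runs x k_classifiers matrix (column names used
#'   for the medians).
#' @return A [FriedmanResult-class].
#' @export
friedmanTest <- function(accMatrix) {
  accMatrix <- as.matrix(accMatrix)
  n <- nrow(accMatrix); k <- ncol(accMatrix)
  if (n < 2L) stop("need at least 2 runs (rows)")
  if (k < 2L) stop("need at least 2 classifiers (columns)")
  if (!all(is.finite(accMatrix))) stop("accuracy matrix must be finite")
  r <- t(apply(accMatrix, 1, rank))  # mid-ranks within each run
  Rj <- colSums(r)
  num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  tieterm <- sum(apply(accMatrix, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  }))
  den <- n * k * (k + 1) - tieterm / (k - 1)
  stat <- if (num == 0) 0 else num / den
  W <- stat / (n * (k - 1))
  f <- if (W >= 1) Inf else sqrt(W / (1 - W))
  meds <- apply(accMatrix, 2, stats::median)
  if (is.null(names(meds)))
    names(meds) <- sprintf("classifier%d", seq_len(k))
  new("FriedmanResult", statistic = stat,
      pValue = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
      kendallsW = W, cohensF = f, nRuns = as.integer(n),
      kClassifiers = as.integer(k), medians = meds)
}

#' Repeated-run comparison of classifiers
#'
#' For each run: a fresh stratified train/test split, a fresh fit of every
#' classifier, and test-set evaluation. The run x classifier accuracy table
#' feeds [friedmanTest()]; per-classifier confusion matrices are summed
#' across runs. A run is defined as an independent seed/resplit repetition.
#'
#' @param ds A [WindowDataset-class].
#' @param classifiers Character vector of classifier names
#'   (see [classifierNames()]).
#' @param nRuns Number of repetitions.
#' @param seed Master seed; run seeds are derived deterministically.
#' @param testFraction Held-out fraction per run.
#' @param control Per-model settings passed to [fitBaseline()].
#' @return List: `reports` (list of [ModelReport-class]), `accuracy`
#'   (nRuns x k matrix), `friedman` (a [FriedmanResult-class], or NULL when
#'   nRuns < 2).
#' @export
compareAll <- function(ds, classifiers = c("decision_tree", "xgboost", "cnn_transformer"),
                       nRuns = 3L, seed = 1L, testFraction = 0.2,
                       control = list()) {
  if (length(classifiers) < 2L) stop("need at least 2 classifiers to compare")
  bad <- setdiff(classifiers, .classifierNames)
  if (length(bad))
    stop("unknown classifier(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(.classifierNames, collapse = ", "))
  set.seed(as.integer(seed))
  runSeeds <- sample.int(.Machine$integer.max - 1L, nRuns)
  acc <- matrix(0, nRuns, length(classifiers),
                dimnames = list(NULL, classifiers))
  confusions <- lapply(classifiers, function(x) matrix(0L, 3L, 3L))
  names(confusions) <- classifiers
  for (run in seq_len(nRuns)) {
    sp <- splitTrainTest(ds, testFraction, seed = runSeeds[run])
    truth <- windowLabels(sp$test)
    for (cl in classifiers) {
      fit <- fitBaseline(cl, sp$train, seed = runSeeds[run],
                         control = control)
      pred <- predictLabels(fit, sp$test)
      ca <- confusionAndAccuracy(truth, pred)
      acc[run, cl] <- ca$accuracy
      confusions[[cl]] <- confusions[[cl]] + ca$confusion
    }
  }
  reports <- lapply(classifiers, function(cl) {
    cm <- confusions[[cl]]
    dimnames(cm) <- list(true = c("joy", "neutral", "sad"),
                         predicted = c("joy", "neutral", "sad"))
    new("ModelReport", classifier = cl, accuracy = mean(acc[, cl]),
        confusion = cm, runAccuracies = acc[, cl])
  })
  names(reports) <- classifiers
  fr <- if (nRuns >= 2L) friedmanTest(acc) else NULL
  list(reports = reports, accuracy = acc, friedman = fr)
}

#' Boxplot of per-run classifier accuracies
#'
#' @param accMatrix Run x classifier accuracy matrix (as returned in
#'   `compareAll()$accuracy`).
#' @param file Optional PNG path; when given the plot is written there.
#' @param ... Passed to [graphics::boxplot()].
#' @return The boxplot statistics, invisibly.
#' @export
accuracyBoxplot <- function(accMatrix, file = NULL, ...) {
  draw <- function() graphics::boxplot(accMatrix, ylab = "accuracy",
                                       las = 2, ...)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
    out <- draw()
  } else out <- draw()
  invisible(out)
}
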