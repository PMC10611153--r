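#' @include AllClasses.R
NULL

.protocolToSamples <- function(protocol, sampleRate) {
  data.frame(label = protocol$label,
             startSample = as.integer(round(protocol$start_s * sampleRate)) + 1L,
             endSample = as.integer(round(protocol$end_s * sampleRate)))
}

.trialColnames <- function(nChannels = 8L) {
  c(sprintf("ch%d_hbo2", seq_len(nChannels)),
    sprintf("ch%d_hb", seq_len(nChannels)))
}

.assembleTrial <- function(hbSeries, protocol, trialId) {
  nc <- length(hbSeries@channelIds)
  if (nc != 8L)
    stop(sprintf("trial matrix assembly expects 8 channels, got %d", nc))
  values <- cbind(t(hbSeries@hbo2), t(hbSeries@hb))
  colnames(values) <- .trialColnames(nc)
  prot <- .protocolToSamples(protocol, hbSeries@sampleRate)
  new("TrialMatrix", values = values, sampleRate = hbSeries@sampleRate,
      protocol = prot, trialId = trialId)
}

#' @describeIn assembleTrialMatrix Assemble from a hemoglobin series plus an
#'   explicit protocol annotation.
#' @export
setMethod("assembleTrialMatrix", "HemoglobinSeries",
  function(x, protocol = NULL, trialId = "trial001") {
    if (is.null(protocol))
      stop("a protocol annotation (label, start_s, end_s) is required")
    .assembleTrial(x, protocol, trialId)
  })

#' @describeIn assembleTrialMatrix Assemble from a trial record (protocol
#'   taken from the record).
#' @export
setMethod("assembleTrialMatrix", "TrialRecord",
  function(x, protocol = NULL, trialId = NULL) {
    .assembleTrial(x@hemoglobin, x@protocol,
                   if (is.null(trialId)) x@trialId else trialId)
  })

.segmentOne <- function(trial, splitNum) {
  p <- trial@protocol
  emo <- p[!is.na(p$label), , drop = FALSE]
  if (nrow(emo) == 0L)
    stop("trial '", trial@trialId, "' has no labeled emotion segments")
  windows <- list(); labels <- integer(); prov <- list()
  for (s in seq_len(nrow(emo))) {
    len <- emo$endSample[s] - emo$startSample[s] + 1L
    if (len %% splitNum != 0L)
      stop(sprintf("split_num = %d does not divide the emotion-segment length of %d samples",
                   splitNum, len))
    wlen <- len %/% splitNum
    for (w in seq_len(splitNum)) {
      i0 <- emo$startSample[s] + (w - 1L) * wlen
      windows[[length(windows) + 1L]] <-
        trial@values[i0:(i0 + wlen - 1L), , drop = FALSE]
      labels <- c(labels, emo$label[s])
      prov[[length(prov) + 1L]] <-
        data.frame(trial = trial@trialId, segment = s, window = w)
    }
  }
  new("WindowDataset", windows = windows, labels = labels,
      provenance = do.call(rbind, prov), splitNum = as.integer(splitNum))
}

#' @describeIn segmentWindows Segment one trial.
#' @export
setMethod("segmentWindows", "TrialMatrix", function(x, splitNum = 8L) {
  splitNum <- as.integer(splitNum)
  if (splitNum < 1L) stop("split_num must be a positive integer")
  .segmentOne(x, splitNum)
})

#' @describeIn segmentWindows Segment a list of trials and pool the windows.
#' @export
setMethod("segmentWindows", "list", function(x, splitNum = 8L) {
  parts <- lapply(x, segmentWindows, splitNum = splitNum)
  new("WindowDataset",
      windows = do.call(c, lapply(parts, function(p) p@windows)),
      labels = do.call(c, lapply(parts, function(p) p@labels)),
      provenance = do.call(rbind, lapply(parts, function(p) p@provenance)),
      splitNum = as.integer(splitNum))
})

.subsetWindows <- function(ds, idx) {
  new("WindowDataset", windows = ds@windows[idx],
      labels = ds@labels[idx],
      provenance = ds@provenance[idx, , drop = FALSE],
      splitNum = ds@splitNum)
}

#' Drop windows by index
#'
#' Quality-based exclusion hook: removes the given windows (e.g. segments a
#' rater flagged) without imposing any automatic criterion.
#'
#' @param ds A [WindowDataset-class].
#' @param exclude Integer indices of windows to drop.
#' @return The reduced [WindowDataset-class].
#' @export
excludeWindows <- function(ds, exclude) {
  if (length(exclude) == 0L) return(ds)
  exclude <- as.integer(exclude)
  if (any(exclude < 1L | exclude > nWindows(ds)))
    stop("exclusion indices out of range")
  .subsetWindows(ds, setdiff(seq_len(nWindows(ds)), exclude))
}

#' Stratified train/test split of a window dataset
#'
#' Splits windows into disjoint train and test sets, stratified by label.
#' Per-stratum test counts use largest-remainder rounding so that the total
#' test count equals `round(n * testFraction)` exactly (e.g. 1600 windows at
#' 0.2 give 1280 train / 320 test).
#'
#' @param ds A [WindowDataset-class].
#' @param testFraction Fraction of windows held out, in (0, 1).
#' @param seed RNG seed; identical seeds give identical partitions.
#' @return A list with elements `train` and `test`, both
#'   [WindowDataset-class].
#' @export
splitTrainTest <- function(ds, testFraction = 0.2, seed = 1L) {
  if (!is.finite(testFraction) || testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1")
  n <- nWindows(ds)
  labs <- windowLabels(ds)
  present <- 0:2
  counts <- vapply(present, function(l) sum(labs == l), integer(1))
  if (any(counts == 0L))
    stop("empty class stratum: no windows for class(es) ",
         paste(present[counts == 0L], collapse = ", "))
  nTest <- round(n * testFraction)
  raw <- counts * testFraction
  base <- floor(raw)
  rem <- nTest - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  } else if (rem < 0) {
    cut <- order(raw - base, decreasing = FALSE)[seq_len(-rem)]
    base[cut] <- base[cut] - 1
  }
  if (any(base < 0) || any(base > counts))
    stop("testFraction incompatible with class counts")
  set.seed(as.integer(seed))
  testIdx <- integer(0)
  for (i in seq_along(present)) {
    stratum <- which(labs == present[i])
    testIdx <- c(testIdx, sample(stratum, base[i]))
  }
  testIdx <- sort(testIdx)
  list(train = .subsetWindows(ds, setdiff(seq_len(n), testIdx)),
       test = .subsetWindows(ds, testIdx))
}

#' Trial-disjoint train/test split
#'
#' Splits windows by their source trial: whole trials are assigned to either
#' side, so no trial contributes windows to both. This is the leakage-free
#' protocol for judging whether a classifier generalizes beyond recordings
#' it has seen: windows of one trial share slow physiological noise, and a
#' window-level split ([splitTrainTest()]) lets that shared context cross
#' the train/test boundary.
#'
#' @param ds A [WindowDataset-class] with trial provenance.
#' @param testFraction Fraction of trials held out, in (0, 1).
#' @param seed RNG seed.
#' @return A list with elements `train` and `test`.
#' @export
splitByTrial <- function(ds, testFraction = 0.2, seed = 1L) {
  if (!is.finite(testFraction) || testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1")
  trials <- unique(provenance(ds)$trial)
  nTest <- max(1L, round(length(trials) * testFraction))
  if (nTest >= length(trials))
    stop("testFraction leaves no training trials")
  set.seed(as.integer(seed))
  testTrials <- sample(trials, nTest)
  isTest <- provenance(ds)$trial %in% testTrials
  list(train = .subsetWindows(ds, which(!isTest)),
       test = .subsetWindows(ds, which(isTest)))
}

#' Across-trial mean waveforms of the 16 feature columns
#'
#' Element-wise mean across trials for each column of the trial matrices,
#' the group-average view of the hemodynamic trends per channel and
#' chromophore.
#'
#' @param trials List of [TrialMatrix-class] objects of identical shape.
#' @return A time x 16 matrix of means.
#' @export
channelAverageWaveforms <- function(trials) {
  if (length(trials) < 1L) stop("need at least one trial")
  dims <- lapply(trials, function(t) dim(t@values))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all trials must have identical matrix dimensions")
  out <- Reduce(`+`, lapply(trials, trialValues)) / length(trials)
  colnames(out) <- colnames(trials[[1]]@values)
  out
}

#' Stack windows into a single matrix
#'
#' Rows are ordered window-major: window 1 rows first, then window 2, etc.
#' Used by the neural classifiers.
#'
#' @param ds A [WindowDataset-class].
#' @return `(nWindows * windowLength) x 16` matrix.
#' @keywords internal
.stackWindows <- function(ds) {
  do.call(rbind, ds@windows)
}

#' Flatten windows to one feature vector per window
#'
#' Row-major per window (all 16 features of time 1, then time 2, ...);
#' used by the classical (vector-input) classifiers.
#'
#' @param ds A [WindowDataset-class].
#' @return `nWindows x (windowLength * 16)` matrix.
#' @export
flattenWindows <- function(ds) {
  t(vapply(ds@windows, function(w) as.vector(t(w)),
           numeric(nrow(ds@windows[[1]]) * ncol(ds@windows[[1]]))))
}
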