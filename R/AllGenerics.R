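#' @include AllGenerics.R
NULL

#' Convert optical-density changes to hemoglobin concentration changes
#'
#' Applies the Modified Beer-Lambert Law: at each time point and channel the
#' dual-wavelength optical-density change is related to the concentration
#' changes of oxy- and deoxy-hemoglobin through a 2x2 linear system, which is
#' solved exactly.
#'
#' @param od An [OpticalDensitySeries-class] object.
#' @param params A [ChromophoreParams-class] object; defaults to the standard
#'   735/850 nm extinction coefficients and differential path factors.
#' @return A [HemoglobinSeries-class] on the same time grid and channel set.
#' @seealso [hbToOd()] for the forward model.
#' @export
setGeneric("odToHb", function(od, params = chromophoreParams()) standardGeneric("odToHb"))

#' Forward Modified Beer-Lambert model: concentrations to optical density
#'
#' Computes the dual-wavelength optical-density change produced by given
#' oxy-/deoxy-hemoglobin concentration changes,
#' \eqn{\Delta A(\lambda) = (\epsilon_{HbO_2}(\lambda)\Delta c_{HbO_2} +
#' \epsilon_{Hb}(\lambda)\Delta c_{Hb}) \cdot d \cdot DPF(\lambda)}.
#' It is the exact inverse of [odToHb()] and drives the simulator's optical
#' output.
#'
#' @param hb A [HemoglobinSeries-class] object.
#' @param params A [ChromophoreParams-class] object.
#' @return An [OpticalDensitySeries-class].
#' @export
setGeneric("hbToOd", function(hb, params = chromophoreParams()) standardGeneric("hbToOd"))

#' Zero-phase low-pass filtering of hemodynamic signals
#'
#' Removes cardiac (1-1.5 Hz), respiratory (~0.4 Hz) and Mayer-wave (0.1 Hz)
#' oscillations with a zero-phase (forward-backward) 4th-order Butterworth
#' low-pass filter, default cutoff 0.09 Hz. Zero-phase filtering preserves the
#' latency of the hemodynamic response.
#'
#' @param x A [HemoglobinSeries-class], [TrialMatrix-class], matrix
#'   (time in rows) or numeric vector.
#' @param cutoff Cutoff frequency in Hz, strictly between 0 and the Nyquist
#'   frequency.
#' @param sampleRate Sampling rate in Hz (only needed for bare
#'   matrices/vectors; series objects carry their own).
#' @return An object of the same class as `x`, filtered along time.
#' @export
setGeneric("lowpassFilter", function(x, cutoff = 0.09, sampleRate = 10) standardGeneric("lowpassFilter"))

#' Assemble the per-trial feature matrix
#'
#' Lays out one recording as a time-by-16 matrix: columns 1-8 are the
#' \eqn{\Delta HbO_2} series of channels 1-8, columns 9-16 the
#' \eqn{\Delta Hb} series of channels 1-8. A standard 960-s trial at 10 Hz
#' yields a 9600 x 16 matrix.
#'
#' @param x A [HemoglobinSeries-class] (with `protocol` supplied) or a
#'   [TrialRecord-class].
#' @param protocol A data frame with columns `label` (integer 0/1/2 or `NA`
#'   for rest), `start_s`, `end_s` (seconds).
#' @param trialId Character identifier attached to the matrix.
#' @return A [TrialMatrix-class].
#' @export
setGeneric("assembleTrialMatrix", function(x, protocol = NULL, trialId = "trial001") standardGeneric("assembleTrialMatrix"))

#' Segment emotion blocks of a trial into labeled windows
#'
#' Each emotion segment (a movie-clip block; rest periods are discarded) is
#' divided into `splitNum` equal, contiguous, non-overlapping windows that
#' inherit the segment's label. For the standard 4-min (2400-sample) segments,
#' `splitNum = 8` yields 30-s windows of 300 samples.
#'
#' @param x A [TrialMatrix-class] or a list of them.
#' @param splitNum Positive integer dividing the segment length.
#' @return A [WindowDataset-class].
#' @export
setGeneric("segmentWindows", function(x, splitNum = 8L) standardGeneric("segmentWindows"))

#' Predicted class labels
#' @param object A fitted classifier.
#' @param newdata A [WindowDataset-class] of windows to classify.
#' @return Integer labels in `{0, 1, 2}`.
#' @export
setGeneric("predictLabels", function(object, newdata) standardGeneric("predictLabels"))

#' Predicted class probabilities
#' @param object A fitted classifier supporting probabilistic output.
#' @param newdata A [WindowDataset-class].
#' @return A numeric matrix, one row per window, columns classes 0..2; rows
#'   sum to 1.
#' @export
setGeneric("predictProba", function(object, newdata) standardGeneric("predictProba"))

#' @rdname accessors
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))
#' @rdname accessors
#' @export
setGeneric("seriesTime", function(x) standardGeneric("seriesTime"))
#' @rdname accessors
#' @export
setGeneric("hbo2", function(x) standardGeneric("hbo2"))
#' @rdname accessors
#' @export
setGeneric("hb", function(x) standardGeneric("hb"))
#' @rdname accessors
#' @export
setGeneric("deltaA", function(x) standardGeneric("deltaA"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))
#' @rdname accessors
#' @export
setGeneric("trialValues", function(x) standardGeneric("trialValues"))
#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("windowLength", function(x) standardGeneric("windowLength"))
#' @rdname accessors
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
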