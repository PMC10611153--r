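#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## ChromophoreParams
## ---------------------------------------------------------------------------

#' Chromophore parameters for the Modified Beer-Lambert Law
#'
#' Holds the working wavelengths, extinction (absorption) coefficients of
#' oxy- and deoxy-hemoglobin, differential path factors (DPF) and the
#' source-detector distance used to convert optical-density changes to
#' concentration changes. Defaults are the standard values for a 735/850 nm
#' prefrontal montage with d = 3 cm:
#'
#' | wavelength (nm) | DPF | eps_HbO2 (cm^-1) | eps_Hb (cm^-1) |
#' |---|---|---|---|
#' | 735 | 6.058 | 0.4646 | 1.2959 |
#' | 850 | 5.5   | 1.1596 | 0.7861 |
#'
#' @slot wavelengths Numeric length 2, nm.
#' @slot epsHbO2,epsHb Numeric length 2, extinction coefficients per
#'   wavelength, cm^-1.
#' @slot dpf Numeric length 2, differential path factor per wavelength
#'   (dimensionless multiplier of the geometric path).
#' @slot d Source-detector distance, cm.
#' @export
setClass("ChromophoreParams",
  representation(wavelengths = "numeric", epsHbO2 = "numeric",
                 epsHb = "numeric", dpf = "numeric", d = "numeric"),
  validity = function(object) {
    msg <- character()
    for (nm in c("wavelengths", "epsHbO2", "epsHb", "dpf"))
      if (length(slot(object, nm)) != 2L)
        msg <- c(msg, sprintf("'%s' must have length 2 (two wavelengths)", nm))
    vals <- c(object@wavelengths, object@epsHbO2, object@epsHb, object@dpf, object@d)
    if (!all(is.finite(vals)) || any(vals <= 0))
      msg <- c(msg, "all parameters must be finite and strictly positive")
    if (length(msg) == 0L) {
      det <- object@epsHb[1] * object@epsHbO2[2] - object@epsHb[2] * object@epsHbO2[1]
      if (abs(det) < 1e-12)
        msg <- c(msg, "extinction-coefficient matrix is singular: epsHb(l1)*epsHbO2(l2) - epsHb(l2)*epsHbO2(l1) = 0")
    }
    if (length(msg)) msg else TRUE
  })

#' @param wavelengths,epsHbO2,epsHb,dpf,d See slots of
#'   [ChromophoreParams-class].
#' @return `chromophoreParams()` returns a validated [ChromophoreParams-class].
#' @rdname ChromophoreParams-class
#' @export
chromophoreParams <- function(wavelengths = c(735, 850),
                              epsHbO2 = c(0.4646, 1.1596),
                              epsHb = c(1.2959, 0.7861),
                              dpf = c(6.058, 5.5),
                              d = 3) {
  new("ChromophoreParams", wavelengths = wavelengths, epsHbO2 = epsHbO2,
      epsHb = epsHb, dpf = dpf, d = d)
}

setMethod("show", "ChromophoreParams", function(object) {
  cat("ChromophoreParams (Modified Beer-Lambert Law)\n")
  cat(sprintf("  d = %g cm\n", object@d))
  for (i in 1:2)
    cat(sprintf("  %g nm: DPF %g, eps_HbO2 %g, eps_Hb %g\n",
                object@wavelengths[i], object@dpf[i],
                object@epsHbO2[i], object@epsHb[i]))
})

## ---------------------------------------------------------------------------
## Time-series containers
## ---------------------------------------------------------------------------

.checkTimeGrid <- function(time, sampleRate) {
  if (length(time) < 2L) return("time axis needs at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) return("time must be strictly increasing")
  if (max(abs(dt - 1 / sampleRate)) > 1e-6)
    return(sprintf("time must be a uniform grid at %g Hz", sampleRate))
  NULL
}

#' Dual-wavelength optical-density change series
#'
#' Per-channel, per-wavelength optical-density changes \eqn{\Delta A(t)}
#' (dimensionless) on a uniform time grid, default 10 Hz.
#'
#' @slot time Numeric vector, seconds, uniform grid.
#' @slot od 3-d array `[channel, wavelength, time]`.
#' @slot wavelengths Numeric length 2, nm.
#' @slot channelIds Integer channel identifiers (default 1..8).
#' @slot sampleRate Sampling rate, Hz.
#' @export
setClass("OpticalDensitySeries",
  representation(time = "numeric", od = "array", wavelengths = "numeric",
                 channelIds = "integer", sampleRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@wavelengths) != 2L)
      msg <- c(msg, "exactly 2 wavelengths are required")
    dm <- dim(object@od)
    if (length(dm) != 3L ||
        dm[1] != length(object@channelIds) ||
        dm[2] != length(object@wavelengths) ||
        dm[3] != length(object@time))
      msg <- c(msg, "'od' must be a [channel, wavelength, time] array matching channelIds/wavelengths/time")
    if (!all(is.finite(object@od))) msg <- c(msg, "optical densities must be finite")
    tmsg <- .checkTimeGrid(object@time, object@sampleRate)
    if (!is.null(tmsg)) msg <- c(msg, tmsg)
    if (length(msg)) msg else TRUE
  })

#' @param time,od,wavelengths,channelIds,sampleRate See slots.
#' @return A validated [OpticalDensitySeries-class].
#' @rdname OpticalDensitySeries-class
#' @export
opticalDensitySeries <- function(time, od, wavelengths = c(735, 850),
                                 channelIds = seq_len(dim(od)[1]),
                                 sampleRate = 10) {
  new("OpticalDensitySeries", time = as.numeric(time), od = od,
      wavelengths = wavelengths, channelIds = as.integer(channelIds),
      sampleRate = sampleRate)
}

#' Oxy-/deoxy-hemoglobin concentration change series
#'
#' Per-channel \eqn{\Delta c_{HbO_2}(t)} and \eqn{\Delta c_{Hb}(t)} in
#' path-length-normalized concentration units (mM cm based on the extinction
#' coefficient units), on a uniform time grid.
#'
#' @slot time Numeric, seconds.
#' @slot hbo2,hb Numeric matrices, channel x time.
#' @slot channelIds Integer channel ids.
#' @slot sampleRate Hz.
#' @export
setClass("HemoglobinSeries",
  representation(time = "numeric", hbo2 = "matrix", hb = "matrix",
                 channelIds = "integer", sampleRate = "numeric"),
  validity = function(object) {
    msg <- character()
    nc <- length(object@channelIds); nt <- length(object@time)
    if (!identical(dim(object@hbo2), c(nc, nt)) ||
        !identical(dim(object@hb), c(nc, nt)))
      msg <- c(msg, "'hbo2' and 'hb' must be channel x time matrices matching channelIds and time")
    if (!all(is.finite(object@hbo2)) || !all(is.finite(object@hb)))
      msg <- c(msg, "concentrations must be finite")
    tmsg <- .checkTimeGrid(object@time, object@sampleRate)
    if (!is.null(tmsg)) msg <- c(msg, tmsg)
    if (length(msg)) msg else TRUE
  })

#' @param time,hbo2,hb,channelIds,sampleRate See slots.
#' @return A validated [HemoglobinSeries-class].
#' @rdname HemoglobinSeries-class
#' @export
hemoglobinSeries <- function(time, hbo2, hb,
                             channelIds = seq_len(nrow(hbo2)),
                             sampleRate = 10) {
  new("HemoglobinSeries", time = as.numeric(time), hbo2 = hbo2, hb = hb,
      channelIds = as.integer(channelIds), sampleRate = sampleRate)
}

.checkProtocol <- function(protocol, maxS) {
  need <- c("label", "start_s", "end_s")
  if (!is.data.frame(protocol) || !all(need %in% names(protocol)))
    return("protocol must be a data.frame with columns label, start_s, end_s")
  if (nrow(protocol)) {
    if (any(protocol$start_s < 0) || any(protocol$end_s > maxS + 1e-9))
      return("protocol segments must lie within the recording")
    if (any(protocol$end_s <= protocol$start_s))
      return("protocol segments must have positive duration")
    o <- order(protocol$start_s)
    if (any(protocol$start_s[o][-1] < protocol$end_s[o][-nrow(protocol)] - 1e-9))
      return("protocol segments must be disjoint")
    lab <- protocol$label[!is.na(protocol$label)]
    if (length(lab) && !all(lab %in% 0:2))
      return("emotion labels must be 0 (joy), 1 (neutral) or 2 (sad)")
  }
  NULL
}

#' One recorded (or simulated) trial
#'
#' A full recording: a [HemoglobinSeries-class] plus the protocol annotation
#' of its segments. Emotion segments carry labels 0 (joy), 1 (neutral),
#' 2 (sad); rest segments carry `NA`.
#'
#' @slot hemoglobin The [HemoglobinSeries-class].
#' @slot protocol Data frame with columns `label`, `start_s`, `end_s`.
#' @slot trialId Character identifier.
#' @export
setClass("TrialRecord",
  representation(hemoglobin = "HemoglobinSeries", protocol = "data.frame",
                 trialId = "character"),
  validity = function(object) {
    tmax <- max(object@hemoglobin@time) + 1 / object@hemoglobin@sampleRate
    msg <- .checkProtocol(object@protocol, tmax)
    if (!is.null(msg)) msg else TRUE
  })

#' @param hemoglobin,protocol,trialId See slots.
#' @return A validated [TrialRecord-class].
#' @rdname TrialRecord-class
#' @export
trialRecord <- function(hemoglobin, protocol, trialId = "trial001") {
  new("TrialRecord", hemoglobin = hemoglobin, protocol = protocol,
      trialId = trialId)
}

#' Per-trial feature matrix
#'
#' Time x 16 layout: columns 1-8 hold \eqn{\Delta HbO_2} of channels 1-8,
#' columns 9-16 \eqn{\Delta Hb} of channels 1-8. The standard 960-s trial at
#' 10 Hz gives 9600 rows. The protocol is carried in samples.
#'
#' @slot values Numeric matrix, time x 16.
#' @slot sampleRate Hz.
#' @slot protocol Data frame with columns `label`, `startSample`, `endSample`
#'   (1-based, inclusive).
#' @slot trialId Character identifier.
#' @export
setClass("TrialMatrix",
  representation(values = "matrix", sampleRate = "numeric",
                 protocol = "data.frame", trialId = "character"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@values) != 16L)
      msg <- c(msg, sprintf("trial matrix must have exactly 16 columns, got %d", ncol(object@values)))
    p <- object@protocol
    need <- c("label", "startSample", "endSample")
    if (!all(need %in% names(p))) {
      msg <- c(msg, "protocol must have columns label, startSample, endSample")
    } else if (nrow(p)) {
      if (any(p$startSample < 1) || any(p$endSample > nrow(object@values)))
        msg <- c(msg, "protocol segments out of matrix bounds")
      if (any(p$endSample < p$startSample))
        msg <- c(msg, "protocol segments must be non-empty")
      o <- order(p$startSample)
      if (nrow(p) > 1 && any(p$startSample[o][-1] <= p$endSample[o][-nrow(p)]))
        msg <- c(msg, "protocol segments must be disjoint")
      lab <- p$label[!is.na(p$label)]
      if (length(lab) && !all(lab %in% 0:2))
        msg <- c(msg, "emotion labels must be in {0,1,2}")
    }
    if (length(msg)) msg else TRUE
  })

#' Labeled fixed-length windows ready for classification
#'
#' Windows are time x 16 matrices cut from emotion segments; each inherits
#' its segment's label (0 joy, 1 neutral, 2 sad). Provenance records the
#' trial, segment and window index of every window.
#'
#' @slot windows List of numeric matrices, all the same dimension.
#' @slot labels Integer vector in `{0,1,2}`.
#' @slot provenance Data frame with columns `trial`, `segment`, `window`.
#' @slot splitNum The subdivision factor used to cut the windows.
#' @export
setClass("WindowDataset",
  representation(windows = "list", labels = "integer",
                 provenance = "data.frame", splitNum = "integer"),
  validity = function(object) {
    msg <- character()
    n <- length(object@windows)
    if (length(object@labels) != n)
      msg <- c(msg, "one label per window required")
    if (nrow(object@provenance) != n)
      msg <- c(msg, "one provenance row per window required")
    if (n > 0) {
      dims <- vapply(object@windows, dim, integer(2))
      if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
        msg <- c(msg, "all windows must share the same dimensions")
      if (!all(object@labels %in% 0:2))
        msg <- c(msg, "labels must be in {0,1,2}")
    }
    if (object@splitNum < 1L) msg <- c(msg, "splitNum must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' @param windows,labels,provenance,splitNum See slots.
#' @return A validated [WindowDataset-class].
#' @rdname WindowDataset-class
#' @export
windowDataset <- function(windows, labels,
                          provenance = data.frame(
                            trial = rep("trial001", length(windows)),
                            segment = seq_along(windows),
                            window = rep(1L, length(windows))),
                          splitNum = 1L) {
  new("WindowDataset", windows = windows, labels = as.integer(labels),
      provenance = provenance, splitNum = as.integer(splitNum))
}

## ---------------------------------------------------------------------------
## Simulation specs
## ---------------------------------------------------------------------------

#' Block-design stimulation protocol
#'
#' The default emulates the standard session: 60 s pre-rest, then three
#' 4-min movie clips (joy, neutral, sad) each followed by 60 s rest, at
#' 10 Hz over 8 channels; 960 s in total.
#'
#' @slot preRestS,clipS,interRestS Durations in seconds.
#' @slot clipOrder Integer labels of the clips in presentation order.
#' @slot sampleRate Hz.
#' @slot nChannels Number of channels.
#' @export
setClass("SimProtocol",
  representation(preRestS = "numeric", clipS = "numeric",
                 interRestS = "numeric", clipOrder = "integer",
                 sampleRate = "numeric", nChannels = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(c(object@preRestS, object@clipS, object@interRestS) < 0))
      msg <- c(msg, "durations must be non-negative")
    if (!all(object@clipOrder %in% 0:2))
      msg <- c(msg, "clipOrder labels must be in {0,1,2}")
    dt <- 1 / object@sampleRate
    durs <- c(object@preRestS, object@clipS, object@interRestS)
    if (any(abs(durs / dt - round(durs / dt)) > 1e-9))
      msg <- c(msg, "durations must be multiples of the sample period")
    if (object@nChannels < 1L) msg <- c(msg, "need at least one channel")
    if (length(msg)) msg else TRUE
  })

#' @param preRestS,clipS,interRestS,clipOrder,sampleRate,nChannels See slots.
#' @return A validated [SimProtocol-class].
#' @rdname SimProtocol-class
#' @export
simProtocol <- function(preRestS = 60, clipS = 240, interRestS = 60,
                        clipOrder = 0:2, sampleRate = 10, nChannels = 8L) {
  new("SimProtocol", preRestS = preRestS, clipS = clipS,
      interRestS = interRestS, clipOrder = as.integer(clipOrder),
      sampleRate = sampleRate, nChannels = as.integer(nChannels))
}

#' Total duration (s) of a protocol
#' @param protocol A [SimProtocol-class].
#' @return Seconds.
#' @export
protocolDuration <- function(protocol) {
  protocol@preRestS + length(protocol@clipOrder) *
    (protocol@clipS + protocol@interRestS)
}

#' Class-dependent hemodynamic effect specification
#'
#' Amplitudes of the sustained \eqn{\Delta HbO_2} trend per (emotion class,
#' channel), the onset time constant of the saturating response, and the
#' (opposite-signed) \eqn{\Delta Hb} coupling ratio. Defaults: joy drives a
#' positive HbO2 response strongest on the right-frontopolar-like channels
#' (7-8), sadness a negative response, the neutral class is near zero.
#'
#' @slot hbo2Amp Numeric 3 x nChannels matrix (rows = classes 0,1,2),
#'   concentration units.
#' @slot tauS Onset time constant, seconds.
#' @slot hbRatio \eqn{\Delta Hb = -hbRatio \cdot \Delta HbO_2} coupling.
#' @export
setClass("EffectSpec",
  representation(hbo2Amp = "matrix", tauS = "numeric", hbRatio = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@hbo2Amp) != 3L)
      msg <- c(msg, "hbo2Amp needs one row per class (3)")
    if (!all(is.finite(object@hbo2Amp)))
      msg <- c(msg, "amplitudes must be finite")
    if (object@tauS <= 0) msg <- c(msg, "tauS must be positive")
    if (object@hbRatio < 0) msg <- c(msg, "hbRatio must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' @param hbo2Amp,tauS,hbRatio See slots.
#' @param nChannels Number of channels for the default amplitude matrix.
#' @return A validated [EffectSpec-class].
#' @rdname EffectSpec-class
#' @export
effectSpec <- function(hbo2Amp = NULL, tauS = 15, hbRatio = 1 / 3,
                       nChannels = 8L) {
  if (is.null(hbo2Amp)) {
    base <- seq(0.5, 1.25, length.out = nChannels)  # stronger toward ch 8
    hbo2Amp <- rbind(joy = 0.06 * base,
                     neutral = 0.005 * base,
                     sad = -0.05 * base)
  }
  new("EffectSpec", hbo2Amp = hbo2Amp, tauS = tauS, hbRatio = hbRatio)
}

#' Physiological and instrumental noise specification
#'
#' Sinusoidal components (random phase per channel) at the physiological
#' bands that contaminate fNIRS: cardiac (1-1.5 Hz), respiration (~0.4 Hz)
#' and Mayer waves (0.1 Hz), plus a slow drift and white noise. Amplitudes
#' are in the same concentration units as the effects; Hb noise is scaled by
#' `hbNoiseScale`.
#'
#' @slot cardiacFreq,respFreq,mayerFreq,driftFreq Hz, below Nyquist.
#' @slot cardiacAmp,respAmp,mayerAmp,driftAmp,whiteSd Amplitudes (>= 0).
#' @slot hbNoiseScale Multiplier applied to all noise on the Hb channel.
#' @export
setClass("NoiseSpec",
  representation(cardiacFreq = "numeric", cardiacAmp = "numeric",
                 respFreq = "numeric", respAmp = "numeric",
                 mayerFreq = "numeric", mayerAmp = "numeric",
                 driftFreq = "numeric", driftAmp = "numeric",
                 whiteSd = "numeric", hbNoiseScale = "numeric"),
  validity = function(object) {
    msg <- character()
    amps <- c(object@cardiacAmp, object@respAmp, object@mayerAmp,
              object@driftAmp, object@whiteSd, object@hbNoiseScale)
    if (any(amps < 0)) msg <- c(msg, "amplitudes must be >= 0")
    fr <- c(object@cardiacFreq, object@respFreq, object@mayerFreq,
            object@driftFreq)
    if (any(fr <= 0) || any(fr >= 5))
      msg <- c(msg, "noise frequencies must lie in (0, 5) Hz (below Nyquist at 10 Hz)")
    if (length(msg)) msg else TRUE
  })

#' @param cardiacFreq,cardiacAmp,respFreq,respAmp,mayerFreq,mayerAmp,driftFreq,driftAmp,whiteSd,hbNoiseScale
#'   See slots.
#' @return A validated [NoiseSpec-class].
#' @rdname NoiseSpec-class
#' @export
noiseSpec <- function(cardiacFreq = 1.2, cardiacAmp = 0.02,
                      respFreq = 0.4, respAmp = 0.02,
                      mayerFreq = 0.1, mayerAmp = 0.03,
                      driftFreq = 0.005, driftAmp = 0.02,
                      whiteSd = 0.02, hbNoiseScale = 1 / 3) {
  new("NoiseSpec", cardiacFreq = cardiacFreq, cardiacAmp = cardiacAmp,
      respFreq = respFreq, respAmp = respAmp, mayerFreq = mayerFreq,
      mayerAmp = mayerAmp, driftFreq = driftFreq, driftAmp = driftAmp,
      whiteSd = whiteSd, hbNoiseScale = hbNoiseScale)
}

## ---------------------------------------------------------------------------
## Model configs and reports
## ---------------------------------------------------------------------------

#' CNN-Transformer architecture configuration
#'
#' Two 1D conv blocks (conv -> batch norm -> ReLU -> max pool, valid padding,
#' stride 1), a position-wise dense embedding, one Transformer block
#' (multi-head self-attention + feed-forward, each with residual add & layer
#' norm), flatten, dropout, a ReLU dense layer and a softmax head. The
#' defaults trace (300, 16) -> (29, 32) -> (29, 32) -> 928 -> 500 -> 3.
#'
#' @slot inputLen Window length in samples (300 = 30 s at 10 Hz).
#' @slot inputFeatures Number of feature columns (16).
#' @slot convFilters Filters per conv block (32).
#' @slot kernel1,kernel2 Kernel sizes of the two conv layers (8, 10).
#' @slot poolSize Max-pool width/stride (3).
#' @slot embedDim,numHeads,ffDim Transformer dimensions (32, 2, 32).
#' @slot dropout Dropout rate before the dense head.
#' @slot headDense Units of the penultimate dense layer (500).
#' @slot nClasses Number of classes (3).
#' @export
setClass("ArchitectureConfig",
  representation(inputLen = "integer", inputFeatures = "integer",
                 convFilters = "integer", kernel1 = "integer",
                 kernel2 = "integer", poolSize = "integer",
                 embedDim = "integer", numHeads = "integer",
                 ffDim = "integer", dropout = "numeric",
                 headDense = "integer", nClasses = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@embedDim %% object@numHeads != 0L)
      msg <- c(msg, sprintf("embedDim (%d) must be divisible by numHeads (%d)",
                            object@embedDim, object@numHeads))
    l1 <- object@inputLen - object@kernel1 + 1L
    if (l1 < 1L)
      msg <- c(msg, "conv layer 1: input shorter than kernel")
    p1 <- l1 %/% object@poolSize
    l2 <- p1 - object@kernel2 + 1L
    if (l1 >= 1L && l2 < 1L)
      msg <- c(msg, "conv layer 2: pooled sequence shorter than kernel")
    if (l1 >= 1L && l2 >= 1L && l2 %/% object@poolSize < 1L)
      msg <- c(msg, "max pool 2: sequence shorter than pool size")
    if (object@dropout < 0 || object@dropout >= 1)
      msg <- c(msg, "dropout must be in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' @param inputLen,inputFeatures,convFilters,kernel1,kernel2,poolSize,embedDim,numHeads,ffDim,dropout,headDense,nClasses
#'   See slots.
#' @return A validated [ArchitectureConfig-class].
#' @rdname ArchitectureConfig-class
#' @export
architectureConfig <- function(inputLen = 300L, inputFeatures = 16L,
                               convFilters = 32L, kernel1 = 8L, kernel2 = 10L,
                               poolSize = 3L, embedDim = 32L, numHeads = 2L,
                               ffDim = 32L, dropout = 0.3, headDense = 500L,
                               nClasses = 3L) {
  new("ArchitectureConfig", inputLen = as.integer(inputLen),
      inputFeatures = as.integer(inputFeatures),
      convFilters = as.integer(convFilters), kernel1 = as.integer(kernel1),
      kernel2 = as.integer(kernel2), poolSize = as.integer(poolSize),
      embedDim = as.integer(embedDim), numHeads = as.integer(numHeads),
      ffDim = as.integer(ffDim), dropout = dropout,
      headDense = as.integer(headDense), nClasses = as.integer(nClasses))
}

#' Sequence lengths through the convolutional front-end
#'
#' @param arch An [ArchitectureConfig-class].
#' @return Named integer vector: lengths after conv1, pool1, conv2, pool2 and
#'   the flattened dimension (`pool2 * convFilters`).
#' @export
convTrace <- function(arch) {
  l1 <- arch@inputLen - arch@kernel1 + 1L
  p1 <- l1 %/% arch@poolSize
  l2 <- p1 - arch@kernel2 + 1L
  p2 <- l2 %/% arch@poolSize
  c(conv1 = l1, pool1 = p1, conv2 = l2, pool2 = p2,
    flatten = p2 * arch@convFilters)
}

setMethod("show", "ArchitectureConfig", function(object) {
  tr <- convTrace(object)
  cat("ArchitectureConfig (CNN-Transformer)\n")
  cat(sprintf("  input (%d, %d) -> conv stack (%d, %d) -> transformer (%d, %d) -> flatten %d -> dense %d -> softmax %d\n",
              object@inputLen, object@inputFeatures, tr["pool2"],
              object@convFilters, tr["pool2"], object@embedDim,
              tr["flatten"], object@headDense, object@nClasses))
  cat(sprintf("  kernels (%d, %d), pool %d, heads %d, ff %d, dropout %g\n",
              object@kernel1, object@kernel2, object@poolSize,
              object@numHeads, object@ffDim, object@dropout))
})

#' Training configuration (plain SGD on cross-entropy)
#'
#' @slot learningRate SGD learning rate (default 0.005).
#' @slot batchSize Mini-batch size (default 32).
#' @slot epochs Number of passes over the training set (default 500).
#' @slot seed RNG seed controlling initialization, shuffling and dropout.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' @param learningRate,batchSize,epochs,seed See slots.
#' @return A validated [TrainConfig-class].
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(learningRate = 0.005, batchSize = 32L, epochs = 500L,
                        seed = 1L) {
  new("TrainConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed))
}

#' Per-classifier evaluation report
#'
#' @slot classifier Classifier name.
#' @slot accuracy Overall accuracy (mean across runs).
#' @slot confusion 3x3 count matrix, rows = true class, cols = predicted,
#'   classes 0 joy / 1 neutral / 2 sad (summed across runs).
#' @slot runAccuracies Accuracy of each repeated run.
#' @export
setClass("ModelReport",
  representation(classifier = "character", accuracy = "numeric",
                 confusion = "matrix", runAccuracies = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@confusion), c(3L, 3L)))
      msg <- c(msg, "confusion must be 3x3")
    if (any(object@confusion < 0)) msg <- c(msg, "confusion counts must be >= 0")
    if (object@accuracy < 0 || object@accuracy > 1)
      msg <- c(msg, "accuracy must be in [0,1]")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ModelReport", function(object) {
  cat(sprintf("ModelReport: %s  accuracy %.3f (%d run%s)\n",
              object@classifier, object@accuracy,
              max(1L, length(object@runAccuracies)),
              if (length(object@runAccuracies) == 1L) "" else "s"))
  print(object@confusion)
})

#' Friedman comparison of classifiers across repeated runs
#'
#' @slot statistic Tie-corrected Friedman chi-square.
#' @slot pValue Upper-tail chi-square p value, k-1 df.
#' @slot kendallsW Kendall's coefficient of concordance, `chi2 / (n (k-1))`.
#' @slot cohensF Effect size `sqrt(W / (1 - W))`.
#' @slot nRuns,kClassifiers Table dimensions.
#' @slot medians Named per-classifier medians.
#' @export
setClass("FriedmanResult",
  representation(statistic = "numeric", pValue = "numeric",
                 kendallsW = "numeric", cohensF = "numeric",
                 nRuns = "integer", kClassifiers = "integer",
                 medians = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@statistic < 0) msg <- c(msg, "statistic must be >= 0")
    if (object@kendallsW < -1e-12 || object@kendallsW > 1 + 1e-12)
      msg <- c(msg, "Kendall's W must be in [0,1]")
    if (object@cohensF < 0) msg <- c(msg, "Cohen's f must be >= 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "FriedmanResult", function(object) {
  cat(sprintf("Friedman test: chi2 = %.3f (df = %d), p = %.4g, n = %d runs x %d classifiers\n",
              object@statistic, object@kClassifiers - 1L, object@pValue,
              object@nRuns, object@kClassifiers))
  cat(sprintf("  Kendall's W = %.3f, Cohen's f = %.3f\n",
              object@kendallsW, object@cohensF))
  cat("  medians:\n")
  print(round(object@medians, 3))
})

#' A fitted classifier with a uniform prediction interface
#'
#' Wraps any of the supported classifiers (classical or neural) behind
#' [predictLabels()] / [predictProba()].
#'
#' @slot name Classifier name.
#' @slot fit The underlying fit object.
#' @slot predictFun Function `(fit, WindowDataset) -> integer labels`.
#' @slot probaFun Function `(fit, WindowDataset) -> probability matrix`, or
#'   NULL when the model has no probabilistic output.
#' @export
setClass("FittedClassifier",
  representation(name = "character", fit = "ANY", predictFun = "function",
                 probaFun = "ANY"))

setMethod("predictLabels", "FittedClassifier", function(object, newdata) {
  object@predictFun(object@fit, newdata)
})

setMethod("predictProba", "FittedClassifier", function(object, newdata) {
  if (is.null(object@probaFun))
    stop("classifier '", object@name, "' has no probabilistic output")
  object@probaFun(object@fit, newdata)
})

setMethod("show", "FittedClassifier", function(object) {
  cat(sprintf("FittedClassifier: %s\n", object@name))
})

## ---------------------------------------------------------------------------
## Accessors and show methods for data containers
## ---------------------------------------------------------------------------

#' Accessors for the package's data containers
#'
#' Small read-only accessors: `channelIds`, `seriesTime`, `hbo2`, `hb`,
#' `deltaA`, `sampleRate`, `protocol`, `trialValues`, `nWindows`,
#' `windowLength`, `windowLabels`, `provenance`, `accuracy`,
#' `confusionMatrix`.
#'
#' @param x A package object.
#' @return The slot content.
#' @name accessors
NULL

setMethod("channelIds", "OpticalDensitySeries", function(x) x@channelIds)
setMethod("channelIds", "HemoglobinSeries", function(x) x@channelIds)
setMethod("seriesTime", "OpticalDensitySeries", function(x) x@time)
setMethod("seriesTime", "HemoglobinSeries", function(x) x@time)
setMethod("hbo2", "HemoglobinSeries", function(x) x@hbo2)
setMethod("hb", "HemoglobinSeries", function(x) x@hb)
setMethod("deltaA", "OpticalDensitySeries", function(x) x@od)
setMethod("sampleRate", "OpticalDensitySeries", function(x) x@sampleRate)
setMethod("sampleRate", "HemoglobinSeries", function(x) x@sampleRate)
setMethod("sampleRate", "TrialMatrix", function(x) x@sampleRate)
setMethod("protocol", "TrialRecord", function(x) x@protocol)
setMethod("protocol", "TrialMatrix", function(x) x@protocol)
setMethod("trialValues", "TrialMatrix", function(x) x@values)
setMethod("nWindows", "WindowDataset", function(x) length(x@windows))
setMethod("windowLength", "WindowDataset", function(x) {
  if (length(x@windows) == 0L) 0L else nrow(x@windows[[1]])
})
setMethod("windowLabels", "WindowDataset", function(x) x@labels)
setMethod("provenance", "WindowDataset", function(x) x@provenance)
setMethod("accuracy", "ModelReport", function(x) x@accuracy)
setMethod("confusionMatrix", "ModelReport", function(x) x@confusion)

setMethod("show", "OpticalDensitySeries", function(object) {
  cat(sprintf("OpticalDensitySeries: %d channels x 2 wavelengths (%g/%g nm) x %d samples at %g Hz (%.1f s)\n",
              length(object@channelIds), object@wavelengths[1],
              object@wavelengths[2], length(object@time), object@sampleRate,
              length(object@time) / object@sampleRate))
})

setMethod("show", "HemoglobinSeries", function(object) {
  cat(sprintf("HemoglobinSeries: %d channels x %d samples at %g Hz (%.1f s), dHbO2/dHb\n",
              length(object@channelIds), length(object@time),
              object@sampleRate, length(object@time) / object@sampleRate))
})

setMethod("show", "TrialRecord", function(object) {
  cat(sprintf("TrialRecord '%s'\n", object@trialId))
  show(object@hemoglobin)
  lab <- object@protocol$label
  cat(sprintf("  protocol: %d segments (%d emotion, %d rest)\n",
              nrow(object@protocol), sum(!is.na(lab)), sum(is.na(lab))))
})

setMethod("show", "TrialMatrix", function(object) {
  cat(sprintf("TrialMatrix '%s': %d x %d at %g Hz, %d protocol segments\n",
              object@trialId, nrow(object@values), ncol(object@values),
              object@sampleRate, nrow(object@protocol)))
})

setMethod("show", "WindowDataset", function(object) {
  n <- length(object@windows)
  cat(sprintf("WindowDataset: %d windows", n))
  if (n) {
    cat(sprintf(" of %d x %d (splitNum %d)\n", nrow(object@windows[[1]]),
                ncol(object@windows[[1]]), object@splitNum))
    cat("  labels: ")
    print(table(factor(object@labels, levels = 0:2,
                       labels = c("joy", "neutral", "sad"))))
  } else cat("\n")
})
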