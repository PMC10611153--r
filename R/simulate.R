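#' @include AllClasses.R
NULL

.protocolSegments <- function(protocol) {
  ## data.frame(label, start_s, end_s) for pre-rest + clips + rests
  segs <- data.frame(label = NA_integer_, start_s = 0, end_s = protocol@preRestS)
  t0 <- protocol@preRestS
  for (lab in protocol@clipOrder) {
    segs <- rbind(segs,
                  data.frame(label = lab, start_s = t0, end_s = t0 + protocol@clipS),
                  data.frame(label = NA_integer_, start_s = t0 + protocol@clipS,
                             end_s = t0 + protocol@clipS + protocol@interRestS))
    t0 <- t0 + protocol@clipS + protocol@interRestS
  }
  segs[segs$end_s > segs$start_s, , drop = FALSE]
}

## Saturating-exponential response to the box-car stimulus: within each
## segment the drive u is constant and the response relaxes toward it,
## y(t) = u + (y0 - u) exp(-(t - t0)/tau)  -- the box-car convolved with a
## first-order (exponential) kernel.
.boxcarResponse <- function(segs, time, amps, tauS) {
  ## amps: per-segment drive amplitude (0 for rest)
  y <- numeric(length(time))
  y0 <- 0
  for (s in seq_len(nrow(segs))) {
    idx <- which(time >= segs$start_s[s] - 1e-9 & time < segs$end_s[s] - 1e-9)
    if (!length(idx)) next
    u <- amps[s]
    rel <- time[idx] - segs$start_s[s]
    y[idx] <- u + (y0 - u) * exp(-rel / tauS)
    tend <- segs$end_s[s] - segs$start_s[s]
    y0 <- u + (y0 - u) * exp(-tend / tauS)
  }
  y
}

#' Noise-free hemodynamic trend of one trial
#'
#' The class-dependent sustained response used by [simulateTrial()], without
#' any noise: per channel, a box-car drive (amplitude set by the emotion
#' class of each segment, zero in rest) convolved with a saturating
#' exponential of time constant `tauS`.
#'
#' @param protocol A [SimProtocol-class].
#' @param effects An [EffectSpec-class].
#' @return List with `time`, `hbo2` and `hb` (channel x time matrices) and
#'   the protocol segment table.
#' @export
simulateTrend <- function(protocol = simProtocol(), effects = effectSpec()) {
  fs <- protocol@sampleRate
  nT <- as.integer(round(protocolDuration(protocol) * fs))
  time <- (seq_len(nT) - 1L) / fs
  segs <- .protocolSegments(protocol)
  nc <- protocol@nChannels
  if (ncol(effects@hbo2Amp) != nc)
    stop(sprintf("effect amplitudes cover %d channels but the protocol has %d",
                 ncol(effects@hbo2Amp), nc))
  hbo2 <- matrix(0, nc, nT)
  for (ch in seq_len(nc)) {
    amps <- ifelse(is.na(segs$label), 0, effects@hbo2Amp[segs$label + 1L, ch])
    hbo2[ch, ] <- .boxcarResponse(segs, time, amps, effects@tauS)
  }
  list(time = time, hbo2 = hbo2, hb = -effects@hbRatio * hbo2, segments = segs)
}

.sinNoise <- function(time, freq, amp, nChannels) {
  ## one sinusoid per channel with random phase
  ph <- stats::runif(nChannels, 0, 2 * pi)
  out <- matrix(0, nChannels, length(time))
  if (amp > 0)
    for (ch in seq_len(nChannels))
      out[ch, ] <- amp * sin(2 * pi * freq * time + ph[ch])
  out
}

.noiseMatrix <- function(time, noise, nChannels, scale = 1) {
  m <- .sinNoise(time, noise@cardiacFreq, scale * noise@cardiacAmp, nChannels) +
    .sinNoise(time, noise@respFreq, scale * noise@respAmp, nChannels) +
    .sinNoise(time, noise@mayerFreq, scale * noise@mayerAmp, nChannels) +
    .sinNoise(time, noise@driftFreq, scale * noise@driftAmp, nChannels)
  if (noise@whiteSd > 0)
    m <- m + matrix(stats::rnorm(nChannels * length(time),
                                 sd = scale * noise@whiteSd),
                    nChannels, length(time))
  m
}

#' Simulate one fNIRS trial
#'
#' Generates a full trial: the class-dependent hemodynamic trend
#' ([simulateTrend()]) plus sinusoidal physiological noise at the cardiac,
#' respiratory, Mayer-wave and drift bands (random phase per channel) and
#' white noise. \eqn{\Delta Hb} carries the opposite-signed coupled trend and
#' independently phased noise scaled by `noise@hbNoiseScale`.
#'
#' @param protocol A [SimProtocol-class].
#' @param effects An [EffectSpec-class].
#' @param noise A [NoiseSpec-class].
#' @param seed RNG seed; identical seeds give bit-identical trials.
#' @param trialId Identifier stored in the record.
#' @return A [TrialRecord-class].
#' @export
simulateTrial <- function(protocol = simProtocol(), effects = effectSpec(),
                          noise = noiseSpec(), seed = 1L,
                          trialId = "trial001") {
  set.seed(as.integer(seed))
  trend <- simulateTrend(protocol, effects)
  nc <- protocol@nChannels
  hbo2 <- trend$hbo2 + .noiseMatrix(trend$time, noise, nc, scale = 1)
  hbv <- trend$hb + .noiseMatrix(trend$time, noise, nc,
                                 scale = noise@hbNoiseScale)
  hbSeries <- hemoglobinSeries(trend$time, hbo2, hbv,
                               channelIds = seq_len(nc),
                               sampleRate = protocol@sampleRate)
  trialRecord(hbSeries, trend$segments, trialId = trialId)
}

.scaleEffects <- function(effects, effectScale) {
  new("EffectSpec", hbo2Amp = effects@hbo2Amp * effectScale,
      tauS = effects@tauS, hbRatio = effects@hbRatio)
}

.scaleNoise <- function(noise, noiseScale) {
  new("NoiseSpec",
      cardiacFreq = noise@cardiacFreq, cardiacAmp = noise@cardiacAmp * noiseScale,
      respFreq = noise@respFreq, respAmp = noise@respAmp * noiseScale,
      mayerFreq = noise@mayerFreq, mayerAmp = noise@mayerAmp * noiseScale,
      driftFreq = noise@driftFreq, driftAmp = noise@driftAmp * noiseScale,
      whiteSd = noise@whiteSd * noiseScale, hbNoiseScale = noise@hbNoiseScale)
}

#' Simulate a multi-trial dataset
#'
#' Independent trials with per-trial seeds derived deterministically from the
#' master seed. Between-trial (inter-participant-like) variability is modeled
#' as a log-normal multiplier on the effect amplitudes, which preserves the
#' sign of every effect.
#'
#' @param nTrials Number of trials (the standard session count is 69).
#' @param protocol,effects,noise Simulation specs.
#' @param seed Master seed.
#' @param effectScale,noiseScale Global multipliers on effect/noise
#'   amplitudes (1 = the default condition; `effectScale = 0` gives a
#'   null dataset with no class information).
#' @param jitterSd Log-sd of the per-trial amplitude jitter (0 disables).
#' @return List of [TrialRecord-class] objects.
#' @export
simulateDataset <- function(nTrials, protocol = simProtocol(),
                            effects = effectSpec(), noise = noiseSpec(),
                            seed = 1L, effectScale = 1, noiseScale = 1,
                            jitterSd = 0.2) {
  if (nTrials < 1L) stop("nTrials must be >= 1")
  set.seed(as.integer(seed))
  trialSeeds <- sample.int(.Machine$integer.max - 1L, nTrials)
  jitters <- if (jitterSd > 0) stats::rlnorm(nTrials, 0, jitterSd) else rep(1, nTrials)
  noiseS <- .scaleNoise(noise, noiseScale)
  lapply(seq_len(nTrials), function(i) {
    eff <- .scaleEffects(effects, effectScale * jitters[i])
    simulateTrial(protocol, eff, noiseS, seed = trialSeeds[i],
                  trialId = sprintf("trial%03d", i))
  })
}
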