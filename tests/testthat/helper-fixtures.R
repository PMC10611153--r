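# Shared fixtures: small, fast simulation scales for module tests. The
# full-scale study conditions are exercised in test-acceptance.R.

# Short block-design protocol: 6 s pre-rest + 3 x (12 s clip + 6 s rest)
# = 60 s = 600 samples at 10 Hz.
tinyProtocol <- function() simProtocol(preRestS = 6, clipS = 12, interRestS = 6)

# Architecture sized for the tiny protocol's windows (clip 120 samples,
# splitNum 4 -> 30-sample windows).
tinyArch <- function(inputLen = 30L) {
  architectureConfig(inputLen = inputLen, inputFeatures = 16L,
                     convFilters = 8L, kernel1 = 5L, kernel2 = 3L,
                     poolSize = 2L, embedDim = 16L, numHeads = 2L,
                     ffDim = 16L, dropout = 0.1, headDense = 32L)
}

# Directly constructed window dataset with class-dependent mean offsets:
# class k windows have mean k * gap on every feature, plus unit noise.
separableWindows <- function(n, len = 30L, gap = 3, seed = 42L) {
  set.seed(seed)
  labels <- rep(0:2, length.out = n)
  windows <- lapply(seq_len(n), function(i)
    matrix(stats::rnorm(len * 16), len, 16) + labels[i] * gap)
  windowDataset(windows, labels,
                provenance = data.frame(trial = sprintf("t%03d", seq_len(n)),
                                        segment = rep(1L, n),
                                        window = rep(1L, n)),
                splitNum = 1L)
}

# A standard-shape trial matrix (9600 x 16) with the canonical protocol
# segment layout, filled with white noise.
standardTrialMatrix <- function(seed = 1L, trialId = "trial001") {
  set.seed(seed)
  values <- matrix(stats::rnorm(9600 * 16, sd = 0.01), 9600, 16)
  prot <- data.frame(label = c(NA, 0L, NA, 1L, NA, 2L, NA),
                     startSample = c(1L, 601L, 3001L, 3601L, 6001L, 6601L, 9001L),
                     endSample = c(600L, 3000L, 3600L, 6000L, 6600L, 9000L, 9600L))
  new("TrialMatrix", values = values, sampleRate = 10, protocol = prot,
      trialId = trialId)
}

# Small hemoglobin series with arbitrary finite values.
randomHemoglobin <- function(nChannels = 8L, nTime = 40L, seed = 3L) {
  set.seed(seed)
  hemoglobinSeries((seq_len(nTime) - 1) / 10,
                   matrix(stats::rnorm(nChannels * nTime), nChannels, nTime),
                   matrix(stats::rnorm(nChannels * nTime), nChannels, nTime),
                   channelIds = seq_len(nChannels))
}
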