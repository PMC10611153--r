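#' @include AllClasses.R
NULL

## Steady-state initial conditions of a direct-form-II-transposed IIR filter,
## for unit step input (so that filtering a constant yields that constant from
## the first sample on).
.lfilterZi <- function(b, a) {
  n <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, n + 1L - length(b)))
  a <- c(a, rep(0, n + 1L - length(a)))
  b <- b / a[1]; a <- a / a[1]
  # companion matrix of a, transposed
  A <- matrix(0, n, n)
  A[1, ] <- -a[2:(n + 1)]
  if (n > 1) A[cbind(2:n, 1:(n - 1))] <- 1
  IminusA <- diag(n) - t(A)
  B <- b[2:(n + 1)] - a[2:(n + 1)] * b[1]
  solve(IminusA, B)
}

## Direct-form-II-transposed filtering of the columns of x with initial
## state zi (n x ncol matrix).
.filterDF2T <- function(b, a, x, zi) {
  n <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, n + 1L - length(b)))
  a <- c(a, rep(0, n + 1L - length(a)))
  b <- b / a[1]; a <- a / a[1]
  nt <- nrow(x); nc <- ncol(x)
  y <- matrix(0, nt, nc)
  z <- zi
  for (t in seq_len(nt)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    if (n > 1) {
      for (i in seq_len(n - 1L))
        z[i, ] <- b[i + 1] * xt + z[i + 1, ] - a[i + 1] * yt
    }
    z[n, ] <- b[n + 1] * xt - a[n + 1] * yt
    y[t, ] <- yt
  }
  y
}

#' Zero-phase IIR filtering with odd-reflection padding
#'
#' Forward-backward application of an IIR filter to the columns of a matrix.
#' The signal is extended at both ends by even (mirror) reflection and the
#' filter state is initialized at its step-input steady state, so a constant
#' input is returned unchanged and edge transients decay inside the discarded
#' padding.
#' The net frequency response is the squared magnitude of the single-pass
#' filter with zero phase.
#'
#' @param b,a Numerator/denominator filter coefficients.
#' @param x Numeric matrix (time in rows) or vector.
#' @return Filtered data, same shape as `x`.
#' @keywords internal
.filtfiltZero <- function(b, a, x, padlen = NULL) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  nfilt <- max(length(a), length(b))
  nt <- nrow(x)
  minWarm <- 3L * (nfilt - 1L)
  if (nt <= minWarm + 1L)
    stop(sprintf("series too short for zero-phase filtering: %d samples <= filter warm-up of %d",
                 nt, minWarm + 1L))
  if (is.null(padlen)) padlen <- minWarm
  padlen <- as.integer(min(padlen, nt - 2L))
  zi <- .lfilterZi(b, a)
  ext <- rbind(x[(padlen + 1L):2, , drop = FALSE], x,
               x[(nt - 1L):(nt - padlen), , drop = FALSE])
  y <- .filterDF2T(b, a, ext, zi %o% ext[1, ])
  y <- y[nrow(y):1, , drop = FALSE]
  y <- .filterDF2T(b, a, y, zi %o% y[1, ])
  y <- y[nrow(y):1, , drop = FALSE]
  y <- y[(padlen + 1L):(padlen + nt), , drop = FALSE]
  if (vec) y[, 1] else y
}

.butterCoef <- function(cutoff, sampleRate, order = 4L) {
  nyq <- sampleRate / 2
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("cutoff must lie strictly between 0 and the Nyquist frequency (%g Hz), got %g",
                 nyq, cutoff))
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  ## reflect enough signal (about 3 filter time constants) that start-up
  ## transients decay inside the discarded padding
  list(b = bf$b, a = bf$a, padlen = ceiling(3 * sampleRate / cutoff))
}

#' @describeIn lowpassFilter Filter the columns of a bare time x feature
#'   matrix.
#' @export
setMethod("lowpassFilter", "matrix", function(x, cutoff = 0.09, sampleRate = 10) {
  co <- .butterCoef(cutoff, sampleRate)
  .filtfiltZero(co$b, co$a, x, co$padlen)
})

#' @describeIn lowpassFilter Filter a numeric vector.
#' @export
setMethod("lowpassFilter", "numeric", function(x, cutoff = 0.09, sampleRate = 10) {
  co <- .butterCoef(cutoff, sampleRate)
  .filtfiltZero(co$b, co$a, x, co$padlen)
})

#' @describeIn lowpassFilter Filter both chromophores of every channel.
#' @export
setMethod("lowpassFilter", "HemoglobinSeries", function(x, cutoff = 0.09, sampleRate = 10) {
  co <- .butterCoef(cutoff, x@sampleRate)
  hemoglobinSeries(x@time,
                   t(.filtfiltZero(co$b, co$a, t(x@hbo2), co$padlen)),
                   t(.filtfiltZero(co$b, co$a, t(x@hb), co$padlen)),
                   channelIds = x@channelIds, sampleRate = x@sampleRate)
})

#' @describeIn lowpassFilter Filter all 16 feature columns of a trial matrix.
#' @export
setMethod("lowpassFilter", "TrialMatrix", function(x, cutoff = 0.09, sampleRate = 10) {
  co <- .butterCoef(cutoff, x@sampleRate)
  new("TrialMatrix", values = .filtfiltZero(co$b, co$a, x@values, co$padlen),
      sampleRate = x@sampleRate, protocol = x@protocol, trialId = x@trialId)
})

#' Magnitude response of the zero-phase low-pass filter
#'
#' Net gain (after forward-backward filtering) of the default Butterworth
#' low-pass at the given frequencies.
#'
#' @param freq Frequencies, Hz.
#' @param cutoff Cutoff, Hz.
#' @param sampleRate Sampling rate, Hz.
#' @param order Butterworth order (a single pass; the zero-phase response is
#'   its square).
#' @return Numeric vector of net gains in (0, 1].
#' @export
filterGain <- function(freq, cutoff = 0.09, sampleRate = 10, order = 4L) {
  co <- .butterCoef(cutoff, sampleRate, order)
  vapply(freq, function(f) {
    z <- exp(1i * 2 * pi * f / sampleRate)
    h <- sum(co$b * z^-(seq_along(co$b) - 1)) /
      sum(co$a * z^-(seq_along(co$a) - 1))
    Mod(h)^2
  }, numeric(1))
}
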