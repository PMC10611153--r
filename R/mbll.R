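#' @include AllClasses.R
NULL

## Extinction matrix: rows = wavelengths, cols = (HbO2, Hb).
.extinctionMatrix <- function(params) {
  rbind(c(params@epsHbO2[1], params@epsHb[1]),
        c(params@epsHbO2[2], params@epsHb[2]))
}

#' @describeIn odToHb Per channel, the 2x2 system
#'   \eqn{\Delta A(\lambda) / (d \cdot DPF(\lambda)) =
#'   \epsilon_{HbO_2}(\lambda)\Delta c_{HbO_2} +
#'   \epsilon_{Hb}(\lambda)\Delta c_{Hb}}
#'   is solved simultaneously for all time points (one LU factorization of the
#'   extinction matrix per channel).
#' @export
setMethod("odToHb", "OpticalDensitySeries", function(od, params = chromophoreParams()) {
  E <- .extinctionMatrix(params)
  if (abs(det(E)) < 1e-12)
    stop("extinction-coefficient matrix is singular; cannot invert the Modified Beer-Lambert system")
  nc <- length(od@channelIds); nt <- length(od@time)
  hbo2 <- matrix(0, nc, nt); hbv <- matrix(0, nc, nt)
  denom <- params@d * params@dpf  # per wavelength
  for (ch in seq_len(nc)) {
    rhs <- rbind(od@od[ch, 1, ] / denom[1],
                 od@od[ch, 2, ] / denom[2])
    sol <- solve(E, rhs)
    hbo2[ch, ] <- sol[1, ]
    hbv[ch, ] <- sol[2, ]
  }
  hemoglobinSeries(od@time, hbo2, hbv, channelIds = od@channelIds,
                   sampleRate = od@sampleRate)
})

#' @describeIn hbToOd Computes
#'   \eqn{\Delta A(\lambda) = (\epsilon_{HbO_2}(\lambda)\Delta c_{HbO_2} +
#'   \epsilon_{Hb}(\lambda)\Delta c_{Hb}) \cdot d \cdot DPF(\lambda)} for both
#'   wavelengths.
#' @export
setMethod("hbToOd", "HemoglobinSeries", function(hb, params = chromophoreParams()) {
  nc <- length(hb@channelIds); nt <- length(hb@time)
  od <- array(0, dim = c(nc, 2L, nt))
  for (w in 1:2) {
    od[, w, ] <- (params@epsHbO2[w] * hb@hbo2 + params@epsHb[w] * hb@hb) *
      params@d * params@dpf[w]
  }
  opticalDensitySeries(hb@time, od, wavelengths = params@wavelengths,
                       channelIds = hb@channelIds, sampleRate = hb@sampleRate)
})
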