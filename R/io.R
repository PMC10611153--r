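#' @include AllClasses.R
NULL

## All numeric CSV output is written at full double precision (17 significant
## digits) so write -> read roundtrips are bit-exact.
.writeCsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read/write hemoglobin and optical-density series as CSV
#'
#' One row per time point. Hemoglobin files use the header
#' `t, ch1_hbo2, ch1_hb, ch2_hbo2, ...`; optical-density files
#' `t, ch1_od735, ch1_od850, ch2_od735, ...` (wavelengths taken from the
#' header). Values are written at full precision so roundtrips are exact.
#'
#' @param x The series to write.
#' @param path CSV file path.
#' @return `readHemoglobinSeries` / `readOpticalDensitySeries` return the
#'   reconstructed object; the writers return `path` invisibly.
#' @name series-io
NULL

#' @rdname series-io
#' @export
writeHemoglobinSeries <- function(x, path) {
  nc <- length(x@channelIds)
  df <- data.frame(t = x@time)
  for (i in seq_len(nc)) {
    df[[sprintf("ch%d_hbo2", x@channelIds[i])]] <- x@hbo2[i, ]
    df[[sprintf("ch%d_hb", x@channelIds[i])]] <- x@hb[i, ]
  }
  .writeCsv(df, path)
  invisible(path)
}

#' @rdname series-io
#' @export
readHemoglobinSeries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  chCols <- grep("^ch[0-9]+_hbo2$", names(df), value = TRUE)
  ids <- as.integer(sub("^ch([0-9]+)_hbo2$", "\\1", chCols))
  hbo2 <- t(as.matrix(df[sprintf("ch%d_hbo2", ids)]))
  hbv <- t(as.matrix(df[sprintf("ch%d_hb", ids)]))
  dimnames(hbo2) <- dimnames(hbv) <- NULL
  dt <- stats::median(diff(df$t))
  hemoglobinSeries(df$t, hbo2, hbv, channelIds = ids, sampleRate = 1 / dt)
}

#' @rdname series-io
#' @export
writeOpticalDensitySeries <- function(x, path) {
  df <- data.frame(t = x@time)
  for (i in seq_along(x@channelIds))
    for (w in 1:2)
      df[[sprintf("ch%d_od%g", x@channelIds[i], x@wavelengths[w])]] <-
        x@od[i, w, ]
  .writeCsv(df, path)
  invisible(path)
}

#' @rdname series-io
#' @export
readOpticalDensitySeries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  odCols <- grep("^ch[0-9]+_od[0-9.]+$", names(df), value = TRUE)
  ids <- sort(unique(as.integer(sub("^ch([0-9]+)_od.*$", "\\1", odCols))))
  wls <- sort(unique(as.numeric(sub("^ch[0-9]+_od", "", odCols))))
  if (length(wls) != 2L)
    stop(sprintf("expected exactly 2 wavelengths in the header, found %d", length(wls)))
  od <- array(0, dim = c(length(ids), 2L, nrow(df)))
  for (i in seq_along(ids))
    for (w in 1:2)
      od[i, w, ] <- df[[sprintf("ch%d_od%g", ids[i], wls[w])]]
  dt <- stats::median(diff(df$t))
  opticalDensitySeries(df$t, od, wavelengths = wls, channelIds = ids,
                       sampleRate = 1 / dt)
}

#' Read/write trial matrices (CSV + JSON protocol sidecar)
#'
#' The matrix goes to CSV (`t` plus the 16 feature columns); the protocol
#' annotation goes to a JSON sidecar as records of
#' `{label, start_s, end_s}` (label `null` for rest). Roundtrips are
#' bit-exact.
#'
#' @param x A [TrialMatrix-class].
#' @param path CSV path.
#' @param protocolPath JSON sidecar path; defaults to `path` with a
#'   `.protocol.json` suffix.
#' @return `readTrialMatrix` returns the [TrialMatrix-class]; the writer
#'   returns `path` invisibly.
#' @name trial-io
NULL

#' @rdname trial-io
#' @export
writeTrialMatrix <- function(x, path,
                             protocolPath = paste0(path, ".protocol.json")) {
  df <- data.frame(t = (seq_len(nrow(x@values)) - 1L) / x@sampleRate)
  vals <- as.data.frame(x@values)
  names(vals) <- colnames(x@values)
  df <- cbind(df, vals)
  .writeCsv(df, path)
  fs <- x@sampleRate
  prot <- data.frame(label = x@protocol$label,
                     start_s = (x@protocol$startSample - 1L) / fs,
                     end_s = x@protocol$endSample / fs)
  jsonlite::write_json(list(trial_id = x@trialId, sample_rate = fs,
                            segments = prot),
                       protocolPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname trial-io
#' @export
readTrialMatrix <- function(path,
                            protocolPath = paste0(path, ".protocol.json")) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(protocolPath, simplifyVector = TRUE)
  fs <- meta$sample_rate
  segs <- as.data.frame(meta$segments)
  if (!"label" %in% names(segs)) segs$label <- NA_integer_
  prot <- data.frame(label = as.integer(segs$label),
                     startSample = as.integer(round(segs$start_s * fs)) + 1L,
                     endSample = as.integer(round(segs$end_s * fs)))
  values <- as.matrix(df[, setdiff(names(df), "t"), drop = FALSE])
  new("TrialMatrix", values = values, sampleRate = fs, protocol = prot,
      trialId = meta$trial_id)
}

#' Read/write window datasets (long CSV with provenance)
#'
#' One row per (window, sample): provenance columns `trial`, `segment`,
#' `window`, `label`, `split_num`, `sample`, then the 16 feature columns.
#'
#' @param ds A [WindowDataset-class].
#' @param path CSV path.
#' @return `readWindowDataset` returns the [WindowDataset-class]; the writer
#'   returns `path` invisibly.
#' @name window-io
NULL

#' @rdname window-io
#' @export
writeWindowDataset <- function(ds, path) {
  n <- nWindows(ds)
  wlen <- windowLength(ds)
  prov <- ds@provenance
  df <- data.frame(
    trial = rep(prov$trial, each = wlen),
    segment = rep(prov$segment, each = wlen),
    window = rep(prov$window, each = wlen),
    label = rep(ds@labels, each = wlen),
    split_num = rep(ds@splitNum, n * wlen),
    sample = rep(seq_len(wlen), n))
  vals <- as.data.frame(do.call(rbind, ds@windows))
  names(vals) <- if (!is.null(colnames(ds@windows[[1]])))
    colnames(ds@windows[[1]]) else .trialColnames(ncol(ds@windows[[1]]) / 2)
  .writeCsv(cbind(df, vals), path)
  invisible(path)
}

#' @rdname window-io
#' @export
readWindowDataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("trial", "segment", "window", "label", "split_num", "sample")
  featCols <- setdiff(names(df), meta)
  key <- interaction(df$trial, df$segment, df$window, drop = TRUE)
  ord <- !duplicated(key)
  windows <- lapply(split(seq_len(nrow(df)), key)[as.character(unique(key))], function(i) {
    m <- as.matrix(df[i, featCols, drop = FALSE])
    rownames(m) <- NULL
    m
  })
  first <- which(ord)
  new("WindowDataset", windows = unname(windows),
      labels = as.integer(df$label[first]),
      provenance = data.frame(trial = df$trial[first],
                              segment = df$segment[first],
                              window = df$window[first]),
      splitNum = as.integer(df$split_num[1]))
}
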