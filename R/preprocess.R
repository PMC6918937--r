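#' Definition of a frequency band
#'
#' @param name rhythm label.
#' @param lo,hi band edges in Hz, `0 < lo < hi`. Bin ownership at the edges
#'   is half-open, `[lo, hi)`, so adjacent bands never share a frequency bin.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, lo, hi) {
  check_that(
    "band edges must satisfy 0 < lo < hi" = is.numeric(lo) && is.numeric(hi) &&
      lo > 0 && lo < hi
  )
  structure(list(name = name, lo = lo, hi = hi), class = "band_definition")
}

#' The five classical EEG rhythms
#'
#' delta 2-4 Hz, theta 4-8 Hz, alpha1 8-10 Hz, alpha2 10-13 Hz and
#' beta 13-30 Hz, with half-open `[lo, hi)` edge ownership (4 Hz belongs to
#' theta, not delta).
#'
#' @return Named list of [band_definition()] objects.
#' @export
eeg_bands <- function() {
  list(
    delta  = band_definition("delta", 2, 4),
    theta  = band_definition("theta", 4, 8),
    alpha1 = band_definition("alpha1", 8, 10),
    alpha2 = band_definition("alpha2", 10, 13),
    beta   = band_definition("beta", 13, 30)
  )
}

#' Resample an epoch set to a lower sampling rate
#'
#' Polyphase rational resampling with anti-alias filtering, applied per
#' epoch and channel. The rational factor is reduced from the two integer
#' rates (1000 to 256 Hz resamples by 32/125).
#'
#' @param epochs an [epoch_set()].
#' @param target_fs new sampling rate in Hz, at most the current rate.
#' @return An `epoch_set` at `target_fs`; each epoch has
#'   `round(n * target_fs / fs)` samples.
#' @export
resample_epochs <- function(epochs, target_fs) {
  check_that(
    "epochs must be an epoch_set" = inherits(epochs, "epoch_set"),
    "target_fs must be positive" = target_fs > 0,
    "target_fs must not exceed the source rate" = target_fs <= epochs$fs,
    "integer sampling rates required" =
      abs(epochs$fs - round(epochs$fs)) < 1e-9 &&
      abs(target_fs - round(target_fs)) < 1e-9
  )
  if (target_fs == epochs$fs) return(epochs)
  g <- gcd_int(round(target_fs), round(epochs$fs))
  p <- round(target_fs) / g
  q <- round(epochs$fs) / g
  d <- dim(epochs$data)
  n_out <- round(d[1] * target_fs / epochs$fs)
  out <- array(0, dim = c(n_out, d[2], d[3]))
  for (e in seq_len(d[3])) {
    for (ch in seq_len(d[2])) {
      y <- signal::resample(epochs$data[, ch, e], p, q)
      out[, ch, e] <- y[seq_len(n_out)]
    }
  }
  epoch_set(out, fs = target_fs, channels = epochs$channels,
            subject = epochs$subject, time_point = epochs$time_point,
            condition = epochs$condition, seed = epochs$seed)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Brick-wall filter of one vector: zero every DFT bin whose |frequency| lies
# outside [lo, hi), then invert. The mask is symmetric in |f|, so the
# inverse transform is real up to rounding.
fft_bandpass <- function(x, lo, hi, fs) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  absf <- pmin(f, fs - f)
  keep <- absf >= lo & absf < hi
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

#' FFT band filtering of an epoch set
#'
#' Each epoch-channel trace is transformed, every frequency bin with
#' absolute frequency outside `[lo, hi)` is zeroed, and the trace is
#' inverse-transformed (real part). This is an exactly linear, idempotent
#' brick-wall filter; it is applied per 5-s epoch, which accepts some edge
#' ringing in exchange for exact band separation.
#'
#' @param epochs an [epoch_set()].
#' @param band a [band_definition()].
#' @return An `epoch_set` of the same shape containing the band component.
#' @export
band_filter <- function(epochs, band) {
  check_that(
    "epochs must be an epoch_set" = inherits(epochs, "epoch_set"),
    "band must be a band_definition" = inherits(band, "band_definition"),
    "band must lie below the Nyquist frequency" = band$hi <= epochs$fs / 2
  )
  d <- dim(epochs$data)
  out <- epochs$data
  for (e in seq_len(d[3])) {
    for (ch in seq_len(d[2])) {
      out[, ch, e] <- fft_bandpass(epochs$data[, ch, e], band$lo, band$hi,
                                   epochs$fs)
    }
  }
  epoch_set(out, fs = epochs$fs, channels = epochs$channels,
            subject = epochs$subject, time_point = epochs$time_point,
            condition = epochs$condition, seed = epochs$seed)
}

#' Decompose an epoch set into EEG rhythms
#'
#' Applies [band_filter()] for every band, preserving order.
#'
#' @param epochs an [epoch_set()].
#' @param bands named list of [band_definition()] objects
#'   (default [eeg_bands()]).
#' @return An object of class `band_decomposition`: a named list of filtered
#'   `epoch_set`s, one per rhythm.
#' @export
decompose <- function(epochs, bands = eeg_bands()) {
  check_that(
    "bands must be a non-empty list of band definitions" =
      is.list(bands) && length(bands) > 0 &&
      all(vapply(bands, inherits, logical(1), "band_definition"))
  )
  nm <- names(bands) %||% vapply(bands, `[[`, character(1), "name")
  out <- lapply(bands, function(b) band_filter(epochs, b))
  names(out) <- nm
  structure(out, class = "band_decomposition")
}

#' @export
print.band_decomposition <- function(x, ...) {
  cat("Band decomposition:", paste(names(x), collapse = " "), "\n")
  print(x[[1]])
  invisible(x)
}
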