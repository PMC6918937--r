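#' Construct an epoch set
#'
#' An epoch set is one subject x time-point x condition block of fixed-length
#' multichannel EEG epochs: a numeric array of dimension
#' `samples x channels x epochs` plus its sampling rate, channel labels, and
#' provenance tags.
#'
#' @param data numeric array `samples x channels x epochs` (a plain matrix is
#'   treated as a single epoch).
#' @param fs sampling rate in Hz.
#' @param channels channel labels, one per column.
#' @param subject,time_point,condition,seed optional provenance tags.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, channels,
                      subject = NA_integer_, time_point = NA_character_,
                      condition = NA_character_, seed = NA_integer_) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  check_that(
    "data must be a numeric samples x channels x epochs array" =
      is.array(data) && length(dim(data)) == 3L && is.numeric(data),
    "all samples must be finite" = all(is.finite(data)),
    "fs must be positive" = is.numeric(fs) && fs > 0,
    "one label per channel required" = length(channels) == dim(data)[2],
    "channel labels must be unique" = !anyDuplicated(channels)
  )
  dimnames(data) <- list(NULL, channels, NULL)
  structure(
    list(data = data, fs = fs, channels = as.character(channels),
         subject = subject, time_point = time_point,
         condition = condition, seed = seed),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set: %d epoch(s) x %d samples x %d channels @ %g Hz\n",
              d[3], d[1], d[2], x$fs))
  if (!is.na(x$subject) || !is.na(x$time_point) || !is.na(x$condition)) {
    cat(sprintf("  subject %s, %s, %s (seed %s)\n",
                x$subject, x$time_point, x$condition, x$seed))
  }
  invisible(x)
}

n_epochs <- function(epochs) dim(epochs$data)[3]
n_samples <- function(epochs) dim(epochs$data)[1]

#' Cut a continuous multichannel recording into fixed-length epochs
#'
#' Non-overlapping windows of `epoch_seconds` are taken from the start of the
#' recording; a trailing partial window is discarded.
#'
#' @param x numeric matrix, samples x channels.
#' @param fs sampling rate in Hz.
#' @param epoch_seconds window length in seconds.
#' @param channels optional channel labels (defaults to column names).
#' @inheritParams epoch_set
#' @return An `epoch_set`.
#' @export
cut_epochs <- function(x, fs, epoch_seconds = 5, channels = colnames(x),
                       subject = NA_integer_, time_point = NA_character_,
                       condition = NA_character_) {
  check_that("x must be a numeric matrix" = is.matrix(x) && is.numeric(x))
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(x)))
  len <- round(fs * epoch_seconds)
  ne <- floor(nrow(x) / len)
  check_that("recording shorter than one epoch" = ne >= 1)
  arr <- array(0, dim = c(len, ncol(x), ne))
  for (e in seq_len(ne)) arr[, , e] <- x[((e - 1) * len + 1):(e * len), ]
  epoch_set(arr, fs = fs, channels = channels, subject = subject,
            time_point = time_point, condition = condition)
}

#' Read a continuous recording from CSV/TSV into an epoch set
#'
#' The file must be a plain numeric samples x channels table with a header
#' row of electrode labels (comma- or tab-separated, chosen by extension).
#'
#' @param path file path.
#' @param fs sampling rate of the stored data in Hz.
#' @param epoch_seconds window length used to epoch the recording.
#' @param ... passed on to [cut_epochs()].
#' @return An `epoch_set`.
#' @export
read_epochs_csv <- function(path, fs, epoch_seconds = 5, ...) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  cut_epochs(as.matrix(df), fs = fs, epoch_seconds = epoch_seconds, ...)
}

#' Write an epoch set to CSV
#'
#' Epochs are concatenated in order into one samples x channels table with a
#' header of electrode labels, the inverse of [read_epochs_csv()] for
#' matching epoch length.
#'
#' @param epochs an `epoch_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epochs_csv <- function(epochs, path) {
  check_that("epochs must be an epoch_set" = inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
  colnames(flat) <- epochs$channels
  utils::write.table(flat, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
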