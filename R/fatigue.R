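#' Band power of a decomposition
#'
#' The power of a rhythm in one epoch-channel trace is the mean of the
#' squared samples of its band-filtered signal (time-domain variance about
#' zero, which for a brick-wall filter equals the PSD integral over the
#' band).
#'
#' @param decomp a `band_decomposition` from [decompose()].
#' @return A long data frame of class `band_power_table` with columns
#'   `epoch`, `channel`, `rhythm`, `power`.
#' @export
band_power <- function(decomp) {
  check_that("decomp must be a band_decomposition" =
               inherits(decomp, "band_decomposition"))
  rows <- lapply(names(decomp), function(b) {
    es <- decomp[[b]]
    d <- dim(es$data)
    p <- apply(es$data^2, c(2, 3), mean)   # channels x epochs
    data.frame(
      epoch = rep(seq_len(d[3]), each = d[2]),
      channel = rep(es$channels, times = d[3]),
      rhythm = b,
      power = as.vector(p)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("band_power_table", "data.frame")
  out
}

#' Spectral fatigue ratio (theta + alpha1 + alpha2) / beta
#'
#' The slow-to-fast power ratio rising with mental fatigue. The ratio is
#' computed per epoch and channel and then averaged over the epochs and the
#' selected channels (by default the nine middle-scalp electrodes), which is
#' robust to single-epoch outliers. Delta is excluded from the index.
#'
#' @param table a `band_power_table` from [band_power()].
#' @param channels channel subset to average over
#'   (default [fatigue_channels()]).
#' @return A single positive number.
#' @examples
#' des <- experiment_design(n_subjects = 1, epochs_per_cell = 2, epoch_seconds = 1)
#' ep <- generate_epoch_set(des, fatigue_trajectory(), 1, "T0", "C2", seed = 1)
#' fatigue_ratio(band_power(decompose(ep)))
#' @export
fatigue_ratio <- function(table, channels = fatigue_channels()) {
  check_that(
    "table must be a band_power_table" = inherits(table, "band_power_table"),
    "all requested channels must be present" =
      all(channels %in% table$channel)
  )
  need <- c("theta", "alpha1", "alpha2", "beta")
  if (!all(need %in% table$rhythm)) {
    stop("band powers for theta, alpha1, alpha2 and beta are required",
         call. = FALSE)
  }
  sub <- table[table$channel %in% channels & table$rhythm %in% need, ]
  wide <- stats::reshape(sub, idvar = c("epoch", "channel"),
                         timevar = "rhythm", direction = "wide")
  pb <- wide$power.beta
  if (any(pb <= 0)) {
    stop("zero beta power in at least one epoch-channel; ratio undefined",
         call. = FALSE)
  }
  mean((wide$power.theta + wide$power.alpha1 + wide$power.alpha2) / pb)
}
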