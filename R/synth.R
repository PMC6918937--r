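# Band-limited Gaussian noise: white noise band-pass filtered with a
# zero-phase Butterworth (applied forward-backward), one second of padding on
# each side absorbing the filter transients. Columns are standardized so the
# variance bookkeeping of the coupling mixtures is exact.
band_noise <- function(n, k, lo, hi, fs, order = 4) {
  pad <- round(fs)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    v <- signal::filtfilt(bf, stats::rnorm(n + 2 * pad))
    v <- v[(pad + 1):(pad + n)]
    out[, j] <- (v - mean(v)) / stats::sd(v)
  }
  out
}

# Base correlation matrix of the channel noise for one rhythm.
# Channels with known scalp positions get a distance-decay correlation
# exp(-d / lambda); `structure` in [0, 1] scales its off-diagonal part.
# Unknown montages fall back to independent channels.
spatial_correlation <- function(channels, lambda, structure = 1) {
  k <- length(channels)
  pos <- electrode_positions()
  if (!all(channels %in% rownames(pos)) || structure == 0) {
    return(diag(k))
  }
  d <- as.matrix(stats::dist(pos[channels, , drop = FALSE]))
  r <- structure * exp(-d / lambda)
  diag(r) <- 1
  r
}

#' Generate one cell of synthetic multichannel EEG
#'
#' Produces the epochs of one subject x time-point x condition cell. Each
#' channel is the sum over the five EEG rhythms of band-limited Gaussian
#' noise (white noise band-pass filtered to the rhythm's band) with
#' amplitudes set by the trajectory's `slow_fast_gain`, and the alpha1
#' component additionally carries the controlled inter-channel dependence:
#' a spatially structured base (distance-decay correlations weighted by
#' `alpha1_structure`) mixed with a single shared alpha1-band source at
#' weight `alpha1_coupling`, `y = sqrt(1 - c) * x + sqrt(c) * s`.
#'
#' The output is deterministic given `(seed, subject, time_point,
#' condition)`: a per-cell child seed is derived from the master seed with
#' [child_seed()].
#'
#' @param design an [experiment_design()].
#' @param trajectory a [fatigue_trajectory()].
#' @param subject subject index in `1:design$n_subjects`.
#' @param time_point one of `design$time_points`.
#' @param condition one of `design$conditions`; when the trajectory has
#'   `task_only_coupling`, conditions other than the last one (the task
#'   state) keep the baseline coupling/structure of the first time point.
#' @param seed master integer seed.
#' @param filter_order Butterworth order for the band-limited noise.
#' @return An [epoch_set()].
#' @examples
#' des <- experiment_design(n_subjects = 1, epochs_per_cell = 2, epoch_seconds = 1)
#' ep <- generate_epoch_set(des, fatigue_trajectory(), 1, "T0", "C2", seed = 1)
#' ep
#' @export
generate_epoch_set <- function(design, trajectory, subject, time_point,
                               condition, seed = 0, filter_order = 4) {
  check_that(
    "design must be an experiment_design" = inherits(design, "experiment_design"),
    "trajectory must be a fatigue_trajectory" =
      inherits(trajectory, "fatigue_trajectory"),
    "trajectory time points must match the design" =
      identical(trajectory$time_points, design$time_points),
    "subject index out of range" =
      subject >= 1 && subject <= design$n_subjects
  )
  ti <- match(time_point, design$time_points)
  ci <- match(condition, design$conditions)
  if (is.na(ti)) stop("unknown time point: ", time_point, call. = FALSE)
  if (is.na(ci)) stop("unknown condition: ", condition, call. = FALSE)

  # the task state is the last condition of the design by convention
  is_task <- ci == length(design$conditions)
  eff_tp <- if (trajectory$task_only_coupling && !is_task) 1L else ti
  gain <- trajectory$slow_fast_gain[ti]          # power ratio rises in both states
  coupling <- trajectory$alpha1_coupling[eff_tp]
  structure_w <- trajectory$alpha1_structure[eff_tp]

  bands <- eeg_bands()
  amp <- trajectory$band_amplitude
  check_that("trajectory band_amplitude must name all five rhythms" =
               all(names(bands) %in% names(amp)))
  slow <- c("theta", "alpha1", "alpha2")

  n <- round(design$fs * design$epoch_seconds)
  k <- length(design$channels)
  ne <- design$epochs_per_cell
  cs <- child_seed(seed, subject, ti, ci)

  chol_sp <- chol(spatial_correlation(design$channels, trajectory$spatial_decay))
  chol_a1 <- chol(spatial_correlation(design$channels, trajectory$spatial_decay,
                                      structure = structure_w))

  data <- with_seed(cs, {
    arr <- array(0, dim = c(n, k, ne))
    for (e in seq_len(ne)) {
      sig <- matrix(0, n, k)
      for (b in names(bands)) {
        a <- amp[[b]] * if (b %in% slow) gain else 1
        if (a == 0) next   # silent rhythm: skip its noise draw entirely
        z <- band_noise(n, k, bands[[b]]$lo, bands[[b]]$hi, design$fs,
                        order = filter_order)
        if (b == "alpha1") {
          x <- z %*% chol_a1
          if (coupling > 0) {
            s <- band_noise(n, 1, bands[[b]]$lo, bands[[b]]$hi, design$fs,
                            order = filter_order)[, 1]
            x <- sqrt(1 - coupling) * x + sqrt(coupling) * s
          }
        } else {
          x <- z %*% chol_sp
        }
        sig <- sig + a * x
      }
      arr[, , e] <- sig
    }
    arr
  })
  epoch_set(data, fs = design$fs, channels = design$channels,
            subject = subject, time_point = time_point,
            condition = condition, seed = cs)
}

#' Generate a connected Watts-Strogatz small-world graph
#'
#' Ring lattice on `n` nodes where each node is linked to its `k` nearest
#' neighbours, followed by random rewiring of each lattice edge's far
#' endpoint with probability `p` (avoiding self-loops and duplicate edges).
#' If the rewired graph is disconnected the construction is retried with the
#' seed incremented, up to a bounded retry budget.
#'
#' @param n number of nodes (`n > k`).
#' @param k even lattice degree (`k >= 2`).
#' @param p rewiring probability in `[0, 1]`.
#' @param seed integer seed.
#' @param max_retries connectivity retry budget.
#' @return A [binary_graph()] on nodes `v1..vn`.
#' @examples
#' g <- generate_ws_graph(19, 4, 0.1, seed = 1)
#' clustering_coefficient(g)
#' @export
generate_ws_graph <- function(n, k, p, seed = 0, max_retries = 100) {
  check_that(
    "need n > k >= 2" = n > k && k >= 2,
    "k must be even" = k %% 2 == 0,
    "p must lie in [0, 1]" = p >= 0 && p <= 1
  )
  for (try in seq_len(max_retries)) {
    adj <- with_seed(seed + try - 1L, {
      a <- matrix(0L, n, n)
      for (i in seq_len(n)) {
        for (off in seq_len(k / 2)) {
          j <- ((i - 1 + off) %% n) + 1
          a[i, j] <- a[j, i] <- 1L
        }
      }
      if (p > 0) {
        for (i in seq_len(n)) {
          for (off in seq_len(k / 2)) {
            j <- ((i - 1 + off) %% n) + 1
            if (stats::runif(1) < p) {
              free <- which(a[i, ] == 0L)
              free <- setdiff(free, i)
              if (length(free) > 0) {
                jj <- free[sample.int(length(free), 1)]
                a[i, j] <- a[j, i] <- 0L
                a[i, jj] <- a[jj, i] <- 1L
              }
            }
          }
        }
      }
      a
    })
    labels <- paste0("v", seq_len(n))
    dimnames(adj) <- list(labels, labels)
    g <- binary_graph(adj)
    if (is_connected_graph(g)) return(g)
  }
  stop("could not generate a connected graph within the retry budget",
       call. = FALSE)
}
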