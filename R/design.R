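#' Standard 19-channel 10-20 electrode labels
#'
#' The recording montage: 19 scalp electrodes of the international 10-20
#' system, in the conventional acquisition order.
#'
#' @return Character vector of 19 electrode labels.
#' @export
standard_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

#' Midline-region channels used for the fatigue ratio
#'
#' The nine electrodes distributed over the middle of the scalp on which the
#' (theta + alpha1 + alpha2)/beta ratio is averaged.
#'
#' @return Character vector of 9 electrode labels.
#' @export
fatigue_channels <- function() {
  c("F3", "C3", "P3", "F4", "C4", "P4", "Fz", "Cz", "Pz")
}

#' Schematic scalp coordinates for the 10-20 montage
#'
#' Two-dimensional grid positions (left-right, front-back) for the 19
#' standard electrodes, in arbitrary "grid units". They are used only to give
#' the synthetic generator a spatial correlation structure with a realistic
#' neighbourhood geometry; they are not head-model coordinates.
#'
#' @return A two-column numeric matrix with electrode labels as row names.
#' @export
electrode_positions <- function() {
  xy <- rbind(
    Fp1 = c(-0.7,  2), Fp2 = c(0.7,  2),
    F7  = c(-1.8,  1), F3  = c(-0.9, 1), Fz = c(0,  1), F4 = c(0.9, 1), F8 = c(1.8, 1),
    T3  = c(-2.0,  0), C3  = c(-1.0, 0), Cz = c(0,  0), C4 = c(1.0, 0), T4 = c(2.0, 0),
    T5  = c(-1.8, -1), P3  = c(-0.9, -1), Pz = c(0, -1), P4 = c(0.9, -1), T6 = c(1.8, -1),
    O1  = c(-0.7, -2), O2  = c(0.7, -2)
  )
  colnames(xy) <- c("x", "y")
  xy[standard_channels(), ]
}

#' Define the recording design of a fatigue experiment
#'
#' Describes the factorial layout of an EEG fatigue session: subjects measured
#' at an ordered series of time points (before/after successive task blocks),
#' each under a resting and a task condition, with a fixed number of
#' artifact-free fixed-length epochs per cell.
#'
#' @param n_subjects number of subjects (default 18).
#' @param time_points ordered character labels of the acquisition times.
#' @param conditions character labels of the recording conditions
#'   (default `C1` rest, `C2` task).
#' @param epochs_per_cell epochs retained per subject x time x condition cell.
#' @param epoch_seconds epoch duration in seconds.
#' @param fs sampling rate in Hz; `fs * epoch_seconds` must be an integer.
#' @param channels electrode labels; defaults to the 19-channel 10-20 montage.
#' @return An object of class `experiment_design`.
#' @examples
#' design <- experiment_design(n_subjects = 2, epochs_per_cell = 3)
#' design
#' @export
experiment_design <- function(n_subjects = 18,
                              time_points = paste0("T", 0:4),
                              conditions = c("C1", "C2"),
                              epochs_per_cell = 10,
                              epoch_seconds = 5,
                              fs = 256,
                              channels = standard_channels()) {
  check_that(
    "n_subjects must be >= 1" = is.numeric(n_subjects) && n_subjects >= 1,
    "time_points must be unique labels" =
      length(time_points) >= 1 && !anyDuplicated(time_points),
    "conditions must be unique labels" =
      length(conditions) >= 1 && !anyDuplicated(conditions),
    "epochs_per_cell must be >= 1" = epochs_per_cell >= 1,
    "fs must be positive" = is.numeric(fs) && fs > 0,
    "channel labels must be unique" = !anyDuplicated(channels),
    "epoch length in samples (fs * epoch_seconds) must be an integer" =
      abs(fs * epoch_seconds - round(fs * epoch_seconds)) < 1e-9
  )
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      time_points = as.character(time_points),
      conditions = as.character(conditions),
      epochs_per_cell = as.integer(epochs_per_cell),
      epoch_seconds = epoch_seconds,
      fs = fs,
      channels = as.character(channels)
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("EEG experiment design\n")
  cat("  subjects:       ", x$n_subjects, "\n")
  cat("  time points:    ", paste(x$time_points, collapse = " "), "\n")
  cat("  conditions:     ", paste(x$conditions, collapse = " "), "\n")
  cat("  epochs/cell:    ", x$epochs_per_cell, "x", x$epoch_seconds, "s\n")
  cat("  sampling rate:  ", x$fs, "Hz\n")
  cat("  channels:       ", length(x$channels), "\n")
  invisible(x)
}

#' Fatigue trajectory driving the synthetic generator
#'
#' A fatigue trajectory gives, for every time point, the parameters that the
#' synthetic generator varies as "fatigue" deepens:
#'
#' * `slow_fast_gain` — multiplier applied to the slow-rhythm amplitudes
#'   (theta, alpha1, alpha2) relative to beta; it drives the
#'   (theta + alpha1 + alpha2)/beta power ratio.
#' * `alpha1_coupling` — weight in `[0, 1)` of a single alpha1-band source
#'   shared by all channels (`y = sqrt(1 - c) * x + sqrt(c) * s`); it drives
#'   the overall level of inter-channel mutual information.
#' * `alpha1_structure` — weight in `[0, 1]` interpolating the base
#'   correlation matrix of the alpha1 channel noise between a spatial
#'   distance-decay structure (1) and a uniform, same-mean correlation (0);
#'   losing structure makes the strongest connections spatially diffuse, so
#'   fixed-degree networks drift from lattice-like towards random.
#'
#' Defaults are read from the packaged configuration file
#' `default_trajectory.yaml` and emulate the canonical fatigue course: the
#' gain rises to T2 then eases, coupling rises to T3 with a dip at T4, and
#' spatial structure decays to T3 then partially recovers. By default the
#' trajectory of `alpha1_coupling`/`alpha1_structure` applies to the *task*
#' condition only; the resting condition stays at the baseline (first time
#' point) values, while `slow_fast_gain` follows the trajectory in both
#' conditions.
#'
#' @param slow_fast_gain numeric vector, one positive gain per time point.
#' @param alpha1_coupling numeric vector in `[0, 1)`, one value per time point.
#' @param alpha1_structure numeric vector in `[0, 1]`, one value per time point.
#' @param time_points character labels; must match the design they are used with.
#' @param band_amplitude named numeric vector of per-rhythm base amplitudes
#'   (standard deviations, arbitrary microvolt-like units).
#' @param spatial_decay correlation decay length in electrode-grid units.
#' @param task_only_coupling logical; if `TRUE` (default) the coupling and
#'   structure trajectories act only in the last (task) condition and the
#'   rest condition is held at baseline.
#' @return An object of class `fatigue_trajectory`.
#' @examples
#' traj <- fatigue_trajectory()
#' traj
#' flat <- null_trajectory()   # no effects at all
#' @export
fatigue_trajectory <- function(slow_fast_gain = NULL,
                               alpha1_coupling = NULL,
                               alpha1_structure = NULL,
                               time_points = NULL,
                               band_amplitude = NULL,
                               spatial_decay = NULL,
                               task_only_coupling = NULL) {
  cfg_path <- system.file("extdata", "default_trajectory.yaml",
                          package = "fatiguenet")
  cfg <- yaml::read_yaml(cfg_path)
  time_points <- time_points %||% as.character(cfg$time_points)
  slow_fast_gain <- slow_fast_gain %||% as.numeric(cfg$slow_fast_gain)
  alpha1_coupling <- alpha1_coupling %||% as.numeric(cfg$alpha1_coupling)
  alpha1_structure <- alpha1_structure %||% as.numeric(cfg$alpha1_structure)
  band_amplitude <- band_amplitude %||% unlist(cfg$band_amplitude)
  spatial_decay <- spatial_decay %||% cfg$spatial_decay
  task_only_coupling <- task_only_coupling %||% cfg$task_only_coupling

  nt <- length(time_points)
  check_that(
    "one slow_fast_gain per time point required" = length(slow_fast_gain) == nt,
    "one alpha1_coupling per time point required" = length(alpha1_coupling) == nt,
    "one alpha1_structure per time point required" = length(alpha1_structure) == nt,
    "slow_fast_gain values must be > 0" = all(slow_fast_gain > 0),
    "alpha1_coupling must lie in [0, 1)" =
      all(alpha1_coupling >= 0 & alpha1_coupling < 1),
    "alpha1_structure must lie in [0, 1]" =
      all(alpha1_structure >= 0 & alpha1_structure <= 1),
    "band_amplitude must be named and non-negative" =
      !is.null(names(band_amplitude)) && all(band_amplitude >= 0),
    "spatial_decay must be positive" = spatial_decay > 0
  )
  structure(
    list(
      time_points = time_points,
      slow_fast_gain = stats::setNames(slow_fast_gain, time_points),
      alpha1_coupling = stats::setNames(alpha1_coupling, time_points),
      alpha1_structure = stats::setNames(alpha1_structure, time_points),
      band_amplitude = band_amplitude,
      spatial_decay = spatial_decay,
      task_only_coupling = isTRUE(task_only_coupling)
    ),
    class = "fatigue_trajectory"
  )
}

#' A trajectory with no effects (flat null)
#'
#' All gains 1, zero shared-source coupling and zero spatial structure at
#' every time point: channels are independent and statistically identical
#' across time, so every downstream contrast is null. Used for type-I error
#' calibration.
#'
#' @param time_points character labels (default T0..T4).
#' @return A `fatigue_trajectory`.
#' @export
null_trajectory <- function(time_points = paste0("T", 0:4)) {
  nt <- length(time_points)
  fatigue_trajectory(
    slow_fast_gain = rep(1, nt),
    alpha1_coupling = rep(0, nt),
    alpha1_structure = rep(0, nt),
    time_points = time_points
  )
}

#' @export
print.fatigue_trajectory <- function(x, ...) {
  cat("Fatigue trajectory over", length(x$time_points), "time points\n")
  m <- rbind(slow_fast_gain = x$slow_fast_gain,
             alpha1_coupling = x$alpha1_coupling,
             alpha1_structure = x$alpha1_structure)
  colnames(m) <- x$time_points
  print(round(m, 3))
  cat("band amplitudes:",
      paste(names(x$band_amplitude), x$band_amplitude, sep = "=", collapse = " "),
      "\n")
  cat("spatial decay:", x$spatial_decay, "grid units;",
      if (x$task_only_coupling) "coupling trajectory acts in task condition only\n"
      else "coupling trajectory acts in all conditions\n")
  invisible(x)
}
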