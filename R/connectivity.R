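#' Histogram mutual-information estimator configuration
#'
#' @param n_bins bins per axis of the 2-D equal-width histogram; `NULL`
#'   (default) selects `ceiling(sqrt(N / 5))` from the sample length `N`
#'   (16 bins for the standard 1280-sample epoch).
#' @param bias_correction subtract the Miller-Madow bias term
#'   `(K_xy - K_x - K_y + 1) / (2N)`, with `K` the occupied joint-cell and
#'   marginal-bin counts.
#' @return An object of class `mi_config`.
#' @export
mi_config <- function(n_bins = NULL, bias_correction = TRUE) {
  if (!is.null(n_bins)) {
    check_that("n_bins must be >= 2" = n_bins >= 2)
    n_bins <- as.integer(n_bins)
  }
  structure(list(n_bins = n_bins, bias_correction = isTRUE(bias_correction)),
            class = "mi_config")
}

resolve_bins <- function(cfg, n) {
  cfg$n_bins %||% as.integer(ceiling(sqrt(n / 5)))
}

# Equal-width bin index of each sample over the vector's own min-max range.
# Returns NULL for a constant vector (zero range).
bin_indices <- function(x, nb) {
  r <- range(x)
  if (r[1] == r[2]) return(NULL)
  ix <- floor((x - r[1]) / (r[2] - r[1]) * nb) + 1L
  ix[ix > nb] <- nb   # the maximum lands in the top bin
  ix
}

# Plug-in MI (nats) from precomputed bin indices, with optional Miller-Madow
# correction, clamped at zero.
mi_from_bins <- function(bx, by, nb, bias_correction = TRUE) {
  n <- length(bx)
  pj <- tabulate(bx + (by - 1L) * nb, nb * nb) / n
  px <- tabulate(bx, nb) / n
  py <- tabulate(by, nb) / n
  pp <- outer(px, py)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / pp[nz]))
  if (bias_correction) {
    mi <- mi - (sum(nz) - sum(px > 0) - sum(py > 0) + 1) / (2 * n)
  }
  max(mi, 0)
}

#' Mutual information between two sample vectors
#'
#' Plug-in estimate from a 2-D equal-width histogram spanning each vector's
#' own range: `MI = sum p_xy * log(p_xy / (p_x p_y))`, in nats, optionally
#' bias-corrected by the Miller-Madow term and clamped at zero (MI is
#' non-negative by definition). A constant input has zero range; its MI is
#' defined as 0 and a warning is raised.
#'
#' @param x,y numeric vectors of equal length (at least `4 * n_bins`
#'   samples).
#' @param cfg an [mi_config()].
#' @return MI estimate in nats.
#' @examples
#' set.seed(1)
#' x <- runif(1280)
#' mutual_information(x, x)            # the entropy of the binned x
#' mutual_information(x, runif(1280))  # near the independence floor
#' @export
mutual_information <- function(x, y, cfg = mi_config()) {
  check_that(
    "x and y must have equal length" = length(x) == length(y),
    "inputs must be finite" = all(is.finite(x)) && all(is.finite(y))
  )
  nb <- resolve_bins(cfg, length(x))
  check_that("need at least 4 * n_bins samples" = length(x) >= 4 * nb)
  bx <- bin_indices(x, nb)
  by <- bin_indices(y, nb)
  if (is.null(bx) || is.null(by)) {
    warning("constant input; mutual information defined as 0")
    return(0)
  }
  mi_from_bins(bx, by, nb, cfg$bias_correction)
}

#' Weighted MI adjacency matrix of an epoch set
#'
#' For every epoch, the MI between all unordered channel pairs is estimated
#' over that epoch's samples; the per-pair estimates are then averaged over
#' the epochs of the set. The result is the symmetric channel x channel
#' matrix of connection weights with a zero diagonal.
#'
#' @param band_epochs an [epoch_set()], typically one rhythm of a
#'   [decompose()] output.
#' @param cfg an [mi_config()].
#' @param rhythm optional rhythm label stored with the matrix.
#' @return An object of class `mi_adjacency`: the weight matrix in `$values`
#'   (with channel dimnames) plus provenance fields.
#' @export
adjacency_from_epochs <- function(band_epochs, cfg = mi_config(),
                                  rhythm = NA_character_) {
  check_that(
    "band_epochs must be an epoch_set" = inherits(band_epochs, "epoch_set"),
    "at least one epoch required" = n_epochs(band_epochs) >= 1
  )
  d <- dim(band_epochs$data)
  k <- d[2]
  nb <- resolve_bins(cfg, d[1])
  w <- matrix(0, k, k)
  n_const <- 0L
  for (e in seq_len(d[3])) {
    bins <- lapply(seq_len(k), function(ch) {
      bin_indices(band_epochs$data[, ch, e], nb)
    })
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (is.null(bins[[i]]) || is.null(bins[[j]])) {
          n_const <- n_const + 1L
        } else {
          w[i, j] <- w[i, j] +
            mi_from_bins(bins[[i]], bins[[j]], nb, cfg$bias_correction)
        }
      }
    }
  }
  if (n_const > 0) {
    warning("constant channel(s) encountered; affected pair MIs set to 0")
  }
  w <- w / d[3]
  w <- w + t(w)
  dimnames(w) <- list(band_epochs$channels, band_epochs$channels)
  structure(
    list(values = w, rhythm = rhythm, subject = band_epochs$subject,
         time_point = band_epochs$time_point,
         condition = band_epochs$condition),
    class = "mi_adjacency"
  )
}

#' @export
print.mi_adjacency <- function(x, ...) {
  k <- nrow(x$values)
  cat(sprintf("MI adjacency %d x %d (%s), mean MI %.4f nats\n",
              k, k, x$rhythm, mean_mi(x)))
  invisible(x)
}

adjacency_values <- function(adj) {
  if (inherits(adj, "mi_adjacency")) adj$values else adj
}

#' Mean connection weight of an adjacency matrix
#'
#' The mean over the strict upper triangle (171 entries for 19 channels) of
#' the full-weighted MI matrix — the summary on which the rhythm-selection
#' ANOVA is run.
#'
#' @param adj an `mi_adjacency` or a plain symmetric matrix.
#' @return A single number.
#' @export
mean_mi <- function(adj) {
  v <- adjacency_values(adj)
  mean(v[upper.tri(v)])
}

#' Write an adjacency matrix as square CSV
#'
#' Header row and first column carry the electrode labels.
#'
#' @param adj an `mi_adjacency` or matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(adj, path) {
  v <- adjacency_values(adj)
  utils::write.csv(as.data.frame(v), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read an adjacency matrix written by [write_adjacency_csv()]
#'
#' @param path file path.
#' @return A numeric matrix with channel dimnames.
#' @export
read_adjacency_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
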