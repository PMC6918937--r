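# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: clustering by explicit triple enumeration,
# path lengths by Floyd-Warshall, MI from an explicit count table.

# adjacency matrix of graph number `mask` on n nodes (bits = upper triangle)
graph_from_mask <- function(mask, n) {
  a <- matrix(0L, n, n)
  ut <- which(upper.tri(a), arr.ind = TRUE)
  bits <- as.integer(intToBits(mask))[seq_len(nrow(ut))]
  a[ut[bits == 1L, , drop = FALSE]] <- 1L
  a + t(a)
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1L)
    k <- length(nb)
    if (k < 2) next
    links <- 0L
    for (u in seq_len(k - 1)) {
      for (v in (u + 1):k) {
        if (a[nb[u], nb[v]] == 1L) links <- links + 1L
      }
    }
    ci[i] <- 2 * links / (k * (k - 1))
  }
  mean(ci)
}

oracle_path_length <- function(a) {
  n <- nrow(a)
  d <- ifelse(a == 1L, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  v <- d[row(d) != col(d)]
  mean(v[is.finite(v)])
}

oracle_connected <- function(a) {
  n <- nrow(a)
  seen <- rep(FALSE, n)
  seen[1] <- TRUE
  repeat {
    nxt <- which(!seen & colSums(a[seen, , drop = FALSE]) > 0)
    if (length(nxt) == 0) break
    seen[nxt] <- TRUE
  }
  all(seen)
}

# plug-in MI (nats) from an explicit joint count table
oracle_mi_from_counts <- function(counts, bias_correction = FALSE) {
  n <- sum(counts)
  pj <- counts / n
  px <- rowSums(pj)
  py <- colSums(pj)
  mi <- 0
  for (i in seq_len(nrow(pj))) {
    for (j in seq_len(ncol(pj))) {
      if (pj[i, j] > 0) {
        mi <- mi + pj[i, j] * log(pj[i, j] / (px[i] * py[j]))
      }
    }
  }
  if (bias_correction) {
    mi <- mi - (sum(counts > 0) - sum(rowSums(counts) > 0) -
                  sum(colSums(counts) > 0) + 1) / (2 * n)
  }
  max(mi, 0)
}

# Erdos-Renyi G(n, m) as a binary_graph, connected by retry
random_gnm_graph <- function(n, m, seed) {
  with_seed(seed, {
    repeat {
      a <- matrix(0L, n, n)
      ut <- which(upper.tri(a))
      a[sample(ut, m)] <- 1L
      a <- a + t(a)
      if (oracle_connected(a)) break
    }
    a
  })
}

# fraction of a signal's periodogram power inside [lo, hi)
band_power_fraction <- function(x, lo, hi, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  inb <- keep & f >= lo & f < hi
  sum(sp[inb]) / sum(sp[keep])
}

tiny_design <- function(n_subjects = 1, epochs = 2, seconds = 2,
                        channels = standard_channels()) {
  experiment_design(n_subjects = n_subjects, epochs_per_cell = epochs,
                    epoch_seconds = seconds, channels = channels)
}
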