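test_that("MI of a variable with itself is the binned entropy", {
  set.seed(1)
  x <- runif(1600)
  cfg <- mi_config(n_bins = 16, bias_correction = FALSE)
  mi <- mutual_information(x, x, cfg)
  counts <- tabulate(pmin(floor((x - min(x)) / diff(range(x)) * 16) + 1, 16), 16)
  p <- counts / length(x)
  expect_equal(mi, -sum(p[p > 0] * log(p[p > 0])), tolerance = 1e-12)
  # near ln(n_bins) for uniform samples
  expect_equal(mi, log(16), tolerance = 0.01)
})

test_that("MI is symmetric and guards its inputs", {
  set.seed(2)
  x <- rnorm(640)
  y <- rnorm(640)
  expect_identical(mutual_information(x, y), mutual_information(y, x))
  expect_error(mutual_information(x, y[-1]), "equal length")
  expect_warning(mi0 <- mutual_information(rep(1, 640), y), "constant")
  expect_identical(mi0, 0)
})

test_that("MI matches an explicit count-table oracle on integer data", {
  set.seed(3)
  for (rep in 1:5) {
    x <- sample(0:3, 200, replace = TRUE)
    y <- (x + sample(0:1, 200, replace = TRUE)) %% 4
    cfg <- mi_config(n_bins = 4, bias_correction = rep %% 2 == 0)
    counts <- matrix(0, 4, 4)
    for (i in seq_along(x)) {
      bx <- min(floor(x[i] / 3 * 4) + 1, 4)
      by <- min(floor(y[i] / 3 * 4) + 1, 4)
      counts[bx, by] <- counts[bx, by] + 1
    }
    expect_equal(mutual_information(x, y, cfg),
                 oracle_mi_from_counts(counts, cfg$bias_correction),
                 tolerance = 1e-12)
  }
})

test_that("bias-corrected MI of independent noise sits near zero", {
  cfg <- mi_config(n_bins = 16)
  mis <- vapply(1:40, function(s) {
    with_seed(s, mutual_information(runif(1280), runif(1280), cfg))
  }, numeric(1))
  expect_lt(quantile(mis, 0.95), 0.05)
})

test_that("MI of a correlated Gaussian approaches the closed form", {
  rho <- 0.9
  target <- -0.5 * log(1 - rho^2)
  mis <- vapply(1:5, function(s) {
    with_seed(100 + s, {
      x <- rnorm(12800)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(12800)
      mutual_information(x, y)
    })
  }, numeric(1))
  expect_lt(abs(mean(mis) - target) / target, 0.15)
})

test_that("adjacency matrices are symmetric with the right extremes", {
  set.seed(9)
  fs <- 256
  base <- rnorm(fs)
  same <- epoch_set(array(rep(base, 19), dim = c(fs, 19, 1)), fs,
                    standard_channels())
  adj <- adjacency_from_epochs(same)
  v <- adj$values
  expect_identical(v, t(v))
  expect_true(all(diag(v) == 0))
  off <- v[upper.tri(v)]
  expect_true(max(abs(off - off[1])) < 1e-12)   # identical channels: equal MI

  indep <- epoch_set(array(rnorm(1280 * 19 * 2), dim = c(1280, 19, 2)),
                     256, standard_channels())
  expect_lt(mean_mi(adjacency_from_epochs(indep)), 0.05)
})

test_that("added independent noise does not raise MI beyond estimator noise", {
  cfg <- mi_config(n_bins = 16)
  deltas <- vapply(1:20, function(s) {
    with_seed(s, {
      x <- rnorm(1280)
      y <- 0.8 * x + 0.6 * rnorm(1280)
      noisy <- x + rnorm(1280)          # corrupt one channel
      mutual_information(x, y, cfg) - mutual_information(noisy, y, cfg)
    })
  }, numeric(1))
  expect_gt(mean(deltas), 0)            # processing cannot create information
})

test_that("mean_mi equals the brute-force upper-triangle mean", {
  set.seed(4)
  m <- matrix(runif(361), 19)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  acc <- 0
  for (i in 1:18) for (j in (i + 1):19) acc <- acc + m[i, j]
  expect_equal(mean_mi(m), acc / 171, tolerance = 1e-14)
  expect_equal(mean_mi(matrix(0, 5, 5)), 0)
  half <- matrix(0.2, 4, 4)
  diag(half) <- 0
  expect_equal(mean_mi(half), 0.2)
})

test_that("adjacency CSV round-trips", {
  set.seed(5)
  m <- matrix(runif(16), 4)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(c("F3", "F4", "C3", "C4"), c("F3", "F4", "C3", "C4"))
  f <- tempfile(fileext = ".csv")
  write_adjacency_csv(m, f)
  expect_equal(read_adjacency_csv(f), m, tolerance = 1e-12)
  unlink(f)
})
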